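#' Exact binomial upper-tail probability
#'
#' Probability of observing at least `k` matching peptides among `n` when
#' each matches by chance with probability `p0`, computed by direct summation
#' of the exact binomial terms (no normal approximation).
#'
#' @param n Number of peptides (trials).
#' @param k Observed matches (successes); `k <= 0` returns 1.
#' @param p0 Chance probability per peptide (see [chance_prob()]).
#' @return `P(X >= k)` for `X ~ Binomial(n, p0)`.
#' @examples
#' binomial_tail(3, 2, chance_prob(0.02, 403))  # 1.939e-4
#' @export
binomial_tail <- function(n, k, p0) {
  if (any(is.na(n)) || any(n < 0)) abort("n must be >= 0.")
  if (any(is.na(p0)) || any(p0 < 0) || any(p0 > 1))
    abort("p0 must be a probability in [0, 1].")
  if (any(k > n)) abort("k must be <= n.")
  mapply(function(n1, k1, p1) {
    if (k1 <= 0) return(1)
    sum(stats::dbinom(k1:n1, n1, p1))
  }, n, k, p0)
}

#' One-sided Fisher's exact contrast
#'
#' Exact hypergeometric tail probability for enrichment of matches in one
#' panel against all others, on the 2x2 table with rows
#' `(k_panel, n_panel - k_panel)` and `(k_other, n_other - k_other)`, by
#' direct summation of hypergeometric terms. The default alternative is one-sided
#' (greater enrichment in the panel); `"two.sided"` sums all tables at most
#' as probable as the observed one.
#'
#' @param k_panel,n_panel Matches and peptide total in the panel of interest.
#' @param k_other,n_other Matches and peptide total in all other panels.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return The exact p-value.
#' @examples
#' fisher_contrast(2, 3, 0, 67)   # 3 / choose(70, 2)
#' fisher_contrast(4, 24, 0, 46)
#' @export
fisher_contrast <- function(k_panel, n_panel, k_other, n_other,
                            alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (any(c(k_panel, n_panel, k_other, n_other) < 0) ||
      k_panel > n_panel || k_other > n_other)
    abort("Counts must be non-negative with k <= n on both sides.")
  c1 <- k_panel + k_other
  xs <- max(0, c1 - n_other):min(n_panel, c1)
  dens <- stats::dhyper(xs, n_panel, n_other, c1)
  p <- if (alternative == "greater") {
    sum(dens[xs >= k_panel])
  } else {
    obs <- dens[xs == k_panel]
    sum(dens[dens <= obs * (1 + 1e-7)])
  }
  min(1, p)
}

# Longest common substring of two strings (used for the motif-collapse rule
# and the reported shared motif).
lcs_pair <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (la == 0 || lb == 0) return("")
  if (la > lb) { tmp <- a; a <- b; b <- tmp; tmp <- la; la <- lb; lb <- tmp }
  for (len in la:1) {
    for (start in 1:(la - len + 1)) {
      sub <- substr(a, start, start + len - 1)
      if (stringr::str_detect(b, stringr::fixed(sub))) return(sub)
    }
  }
  ""
}

lcs_many <- function(strings) {
  out <- strings[1]
  for (s in strings[-1]) {
    out <- lcs_pair(out, s)
    if (nchar(out) == 0) break
  }
  out
}

#' Collapse motif-redundant matches of one panel to one protein
#'
#' Peptides that all match a protein through one shared motif at one site are
#' a single independent piece of evidence, not multiple: the match multiplicity
#' is an artifact of the shared motif. Given the (deduplicated, one best hit
#' per peptide) hits of one panel to one protein, peptides are grouped
#' transitively: two peptides fall in one group when their matched protein
#' intervals overlap *and* their matched substrings share a common substring
#' of at least 4 residues. The effective match count `k_eff` is the number of
#' groups; when everything collapses to one group of two or more peptides,
#' the longest substring common to all matched substrings is reported as the
#' shared motif.
#'
#' @param hits Hit tibble rows for one (panel, protein): columns `sequence`,
#'   `p_start`, `p_end`, `matched_substring`.
#' @param min_shared Minimum shared-substring length for two matches to be
#'   considered redundant (default 4).
#' @return A list with `k_eff`, `shared_motif` (`NA` unless a single group
#'   of two or more peptides remains) and `groups` (integer group index per
#'   row).
#' @export
collapse_motif_redundancy <- function(hits, min_shared = 4L) {
  k <- nrow(hits)
  if (k == 0) return(list(k_eff = 0L, shared_motif = NA_character_,
                          groups = integer(0)))
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (k > 1 && !all(is.na(hits$matched_substring))) {
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        overlap <- hits$p_start[i] <= hits$p_end[j] &&
          hits$p_start[j] <= hits$p_end[i]
        if (!overlap) next
        shared <- lcs_pair(hits$matched_substring[i], hits$matched_substring[j])
        if (nchar(shared) >= min_shared) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  groups <- match(roots, unique(roots))
  k_eff <- length(unique(groups))
  shared_motif <- NA_character_
  if (k_eff == 1 && k >= 2) {
    m <- lcs_many(hits$matched_substring)
    if (nchar(m) >= min_shared) shared_motif <- m
  }
  list(k_eff = k_eff, shared_motif = shared_motif, groups = groups)
}

#' Rank candidate antigen proteins per panel
#'
#' For every (panel, protein) pair with at least one matching peptide:
#' deduplicate to one best hit per peptide, collapse motif-redundant matches
#' to `k_eff` independent matches, and score the protein with (i) the exact
#' binomial tail probability of `k_eff` or more chance matches among the
#' panel's `n` matchable peptides at the length-normalized chance probability
#' `p0 = f * L / 1000`, and (ii) a one-sided Fisher's exact contrast of
#' `k_eff / n` against the matches the same protein drew from all other
#' panels. Candidates are sorted by binomial p, then Fisher p, then protein
#' length, then id.
#'
#' Flags: `MOTIF_COLLAPSED` when `k_eff < k`; `LENGTH_SUSPECT` when the
#' expected number of chance matches `n * p0` reaches the observed `k` (the
#' very-large-protein situation in which multiple matches are explained by
#' chance alone); `EXPRESSION_SUPPORTED` via [expression_cross_check()].
#' Benjamini-Hochberg q-values are reported per panel over proteins with
#' `k >= 2` but are not used for ranking.
#'
#' @param hits Hit tibble from [search_panels()] (or [external_to_hits()]).
#' @param panels Panel tibble the hits came from.
#' @param proteome Proteome tibble (or any tibble with `protein_id` and
#'   `length_aa`; sequences are not needed here).
#' @param null A [null_estimate()]. Forward and null searches must have used
#'   the identical [match_params()] object; a mismatch (including an
#'   internal-vs-external mix) is a hard error.
#' @param exclude_panels Panel ids to leave out of the Fisher "other" group
#'   (e.g. a healthy-control panel); by default all other panels count.
#' @param alternative Sidedness of the Fisher contrast (default one-sided
#'   `"greater"`).
#' @param weight_by_copies Count phage copies instead of unique inserts in
#'   `n` and `k` (off by default: the statistics count distinct sequences).
#' @param min_shared Shared-substring length for the motif collapse
#'   (default 4).
#' @return A `candidate_results` tibble: `panel_id`, `protein_id`,
#'   `length_aa`, `n`, `k`, `k_eff`, `shared_motif`, `p_binomial`,
#'   `p_fisher`, `other_matches`, `other_total`, `q_value`, `flags`,
#'   `rank` (within panel).
#' @export
rank_candidates <- function(hits, panels, proteome, null,
                            exclude_panels = NULL,
                            alternative = c("greater", "two.sided"),
                            weight_by_copies = FALSE, min_shared = 4L) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(null, "null_estimate"))
  hit_params <- attr(hits, "match_params")
  if (!identical(hit_params, null$params))
    abort(paste0(
      "Forward hits and null estimate were not produced with identical match ",
      "parameters (or mix the built-in matcher with external results); ",
      "re-run both stages with one shared parameter object."))
  wmin <- if (!is.null(hit_params)) min_peptide_length(hit_params) else 4L

  eligible <- panels %>%
    dplyr::filter(nchar(.data$sequence) >= wmin)
  dropped <- nrow(panels) - nrow(eligible)
  if (dropped > 0)
    inform(sprintf("%d peptide(s) shorter than %d aa excluded from panel sizes.",
                   dropped, wmin))
  panel_sizes <- eligible %>%
    dplyr::group_by(.data$panel_id) %>%
    dplyr::summarise(n = if (weight_by_copies) sum(.data$copy_number)
                     else dplyr::n(), .groups = "drop")

  hits <- dedupe_hits(hits)
  if (nrow(hits) == 0) {
    out <- empty_report(); out$rank <- integer(0)
    return(structure(out, class = c("candidate_results", class(out))))
  }
  copies <- eligible %>%
    dplyr::distinct(.data$panel_id, .data$sequence, .data$copy_number)
  hits <- hits %>% dplyr::left_join(copies, by = c("panel_id", "sequence"))

  # distinct matching peptides per (panel, protein), weighted variant uses
  # phage copies
  per_pp <- hits %>%
    dplyr::group_by(.data$panel_id, .data$protein_id) %>%
    dplyr::group_map(function(g, key) {
      cl <- collapse_motif_redundancy(g, min_shared = min_shared)
      k <- if (weight_by_copies) sum(g$copy_number) else nrow(g)
      k_eff <- if (weight_by_copies) {
        sum(vapply(split(g$copy_number, cl$groups), max, numeric(1)))
      } else cl$k_eff
      tibble::tibble(panel_id = key$panel_id, protein_id = key$protein_id,
                     k = as.integer(k), k_eff = as.integer(k_eff),
                     shared_motif = cl$shared_motif)
    }) %>%
    dplyr::bind_rows()

  other_pool <- per_pp %>%
    dplyr::filter(!.data$panel_id %in% (exclude_panels %||% character(0)))
  pool_sizes <- panel_sizes %>%
    dplyr::filter(!.data$panel_id %in% (exclude_panels %||% character(0)))

  res <- per_pp %>%
    dplyr::left_join(proteome[, c("protein_id", "length_aa")], by = "protein_id") %>%
    dplyr::left_join(panel_sizes, by = "panel_id")
  if (anyNA(res$length_aa))
    abort("Hits reference protein id(s) absent from the proteome table.")

  res$other_matches <- vapply(seq_len(nrow(res)), function(i) {
    sum(other_pool$k[other_pool$protein_id == res$protein_id[i] &
                       other_pool$panel_id != res$panel_id[i]])
  }, numeric(1)) %>% as.integer()
  res$other_total <- vapply(res$panel_id, function(p) {
    sum(pool_sizes$n[pool_sizes$panel_id != p])
  }, numeric(1)) %>% as.integer()

  p0 <- chance_prob(null$f_mean, res$length_aa)
  res$p_binomial <- binomial_tail(res$n, res$k_eff, p0)
  res$p_fisher <- mapply(fisher_contrast, res$k_eff, res$n,
                         res$other_matches, res$other_total,
                         MoreArgs = list(alternative = alternative))
  res$flags <- purrr::map2_chr(
    res$k_eff < res$k, res$n * p0 >= res$k,
    function(mc, ls) paste(c(if (mc) "MOTIF_COLLAPSED",
                             if (ls) "LENGTH_SUSPECT"), collapse = ","))
  res <- res %>%
    dplyr::group_by(.data$panel_id) %>%
    dplyr::mutate(q_value = {
      q <- rep(NA_real_, dplyr::n())
      sel <- .data$k >= 2
      q[sel] <- stats::p.adjust(.data$p_binomial[sel], method = "BH")
      q
    }) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$panel_id, .data$p_binomial, .data$p_fisher,
                   .data$length_aa, .data$protein_id) %>%
    dplyr::group_by(.data$panel_id) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    dplyr::ungroup() %>%
    dplyr::select("panel_id", "protein_id", "length_aa", "n", "k", "k_eff",
                  "shared_motif", "p_binomial", "p_fisher", "other_matches",
                  "other_total", "q_value", "flags", "rank")
  structure(res, class = c("candidate_results", class(res)),
            null = glance.null_estimate(null), match_params = hit_params)
}

#' Biopanning enrichment quality control
#'
#' A selection is considered successful when the phage titer recovered on the
#' patient's antibodies is at least twice the titer recovered on control
#' antibodies from healthy donors.
#'
#' @param cfu_panel Colony-forming units on the patient antibodies.
#' @param cfu_control Colony-forming units on the control antibodies
#'   (must be >= 1).
#' @param min_ratio Pass threshold (default 2).
#' @return A tibble with `cfu_panel`, `cfu_control`, `ratio`, `pass`;
#'   vectorized.
#' @export
enrichment_qc <- function(cfu_panel, cfu_control, min_ratio = 2) {
  if (any(is.na(cfu_panel)) || any(cfu_panel < 0))
    abort("cfu_panel must be a non-negative count.")
  if (any(is.na(cfu_control)) || any(cfu_control < 1))
    abort("cfu_control must be >= 1 (a zero-titer control cannot normalize the ratio).")
  ratio <- cfu_panel / cfu_control
  tibble::tibble(cfu_panel = cfu_panel, cfu_control = cfu_control,
                 ratio = ratio, pass = ratio >= min_ratio)
}

#' Cross-check candidates against tumor gene expression
#'
#' A candidate antigen gains support when its gene is overexpressed uniquely
#' in the matching patient's own tumor: the expression value in that sample
#' must be at least `fold_threshold` times the maximum over all other
#' samples. Candidates whose protein cannot be mapped to a gene are left
#' unflagged with a warning.
#'
#' @param candidates Candidate tibble from [rank_candidates()].
#' @param expression Tibble of expression values: a `gene_id` column plus one
#'   numeric column per sample.
#' @param gene_map Two-column tibble mapping `protein_id` to `gene_id`.
#' @param patient_sample_map Two-column tibble mapping `patient_id` to the
#'   patient's own tumor `sample_id`.
#' @param fold_threshold Fold-change over the best other sample (default 2).
#' @return `candidates` with `EXPRESSION_SUPPORTED` appended to `flags` where
#'   supported.
#' @export
expression_cross_check <- function(candidates, expression, gene_map,
                                   patient_sample_map, fold_threshold = 2) {
  samples <- setdiff(names(expression), "gene_id")
  patient <- stringr::str_extract(candidates$panel_id, "^[^/]+")
  own_sample <- patient_sample_map$sample_id[
    match(patient, patient_sample_map$patient_id)]
  gene <- gene_map$gene_id[match(candidates$protein_id, gene_map$protein_id)]
  unmapped <- is.na(gene) & !is.na(candidates$protein_id)
  if (any(unmapped))
    warn(paste0("No gene mapping for protein id(s): ",
                paste(unique(candidates$protein_id[unmapped]), collapse = ", "),
                "; left unflagged."))
  supported <- vapply(seq_len(nrow(candidates)), function(i) {
    if (is.na(gene[i]) || is.na(own_sample[i])) return(FALSE)
    row <- expression[expression$gene_id == gene[i], , drop = FALSE]
    if (nrow(row) == 0) return(FALSE)
    own <- as.numeric(row[[own_sample[i]]])
    others <- as.numeric(unlist(row[setdiff(samples, own_sample[i])]))
    length(others) > 0 && is.finite(own) && own >= fold_threshold * max(others)
  }, logical(1))
  candidates$flags <- ifelse(
    supported,
    ifelse(candidates$flags == "" | is.na(candidates$flags),
           "EXPRESSION_SUPPORTED",
           paste0(candidates$flags, ",EXPRESSION_SUPPORTED")),
    candidates$flags)
  candidates
}
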
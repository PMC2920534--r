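#' Matcher parameters for the short-peptide homology search
#'
#' The matcher replaces a protein-BLAST search tuned for very short queries
#' with two transparent modes. `exact` (the default) reports every maximal
#' ungapped window of at least `min_exact_window` residues shared between
#' peptide and protein with at most `max_mismatches` substitutions —
#' appropriate because serum-antibody-recognized motifs are typically 4-6
#' residues and matches of interest are identical or nearly identical.
#' `scored` approximates short-query protein-search conventions: every exact
#' `word_size`-mer seeds an ungapped extension under a substitution matrix
#' (PAM30 by default) and alignments scoring at least `min_score` are
#' reported.
#'
#' @param mode `"exact"` or `"scored"`.
#' @param min_exact_window Minimum shared-window length, >= 4 (default 5;
#'   window 4 reproduces 4-mer motif matches but is noisier).
#' @param max_mismatches Substitution budget within a window (default 0);
#'   must be smaller than `min_exact_window`.
#' @param score_matrix Name of the substitution matrix for scored mode
#'   (default `"PAM30"`; any matrix shipped with Biostrings).
#' @param word_size Exact seed length for scored mode (default 2).
#' @param min_score Minimum ungapped alignment score for scored mode
#'   (default 35).
#' @return A `match_params` object.
#' @export
match_params <- function(mode = c("exact", "scored"), min_exact_window = 5L,
                         max_mismatches = 0L, score_matrix = "PAM30",
                         word_size = 2L, min_score = 35L) {
  mode <- match.arg(mode)
  min_exact_window <- as.integer(min_exact_window)
  max_mismatches <- as.integer(max_mismatches)
  if (is.na(min_exact_window) || min_exact_window < 4)
    abort("min_exact_window must be >= 4 (antibody-recognized motifs are 4-6 aa).")
  if (is.na(max_mismatches) || max_mismatches < 0 ||
      max_mismatches >= min_exact_window)
    abort("max_mismatches must be >= 0 and < min_exact_window.")
  structure(list(mode = mode, min_exact_window = min_exact_window,
                 max_mismatches = max_mismatches,
                 score_matrix = score_matrix,
                 word_size = as.integer(word_size),
                 min_score = as.integer(min_score)),
            class = "match_params")
}

#' @export
print.match_params <- function(x, ...) {
  if (x$mode == "exact") {
    cat(sprintf("<match_params> exact mode: window >= %d, <= %d mismatch(es)\n",
                x$min_exact_window, x$max_mismatches))
  } else {
    cat(sprintf("<match_params> scored mode: %s, word size %d, min score %d\n",
                x$score_matrix, x$word_size, x$min_score))
  }
  invisible(x)
}

# Minimum peptide length a parameter set can match.
min_peptide_length <- function(params) {
  if (params$mode == "exact") params$min_exact_window else params$word_size
}

# Load a Biostrings substitution matrix restricted to the 20 standard
# residues, in this package's residue order.
load_score_matrix <- function(name) {
  env <- new.env()
  ok <- tryCatch({utils::data(list = name, package = "Biostrings", envir = env); TRUE},
                 warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(name, envir = env))
    abort(paste0("Unknown substitution matrix: ", name))
  m <- get(name, envir = env)
  storage.mode(m) <- "integer"
  m[AA_STANDARD, AA_STANDARD]
}

# Core search over peptide and protein character vectors; returns the raw hit
# tibble with 1-based inclusive coordinates. Order: peptide index, protein
# index, position.
search_core <- function(pep_seqs, prot_seqs, params) {
  stopifnot(inherits(params, "match_params"))
  if (params$mode == "exact") {
    raw <- cpp_search_exact(pep_seqs, prot_seqs, params$min_exact_window,
                            params$max_mismatches)
  } else {
    smat <- load_score_matrix(params$score_matrix)
    raw <- cpp_search_scored(pep_seqs, prot_seqs, smat, params$word_size,
                             params$min_score)
  }
  raw <- tibble::as_tibble(raw)
  raw <- raw[order(raw$pep_i, raw$prot_i, raw$prot_start, raw$pep_off), ]
  tibble::tibble(
    pep_i = raw$pep_i, prot_i = raw$prot_i,
    p_start = raw$prot_start + 1L, p_end = raw$prot_start + raw$len,
    pep_start = raw$pep_off + 1L, score = raw$score
  )
}

#' Find matches of one peptide within one protein
#'
#' @param peptide A peptide sequence (or one-row panel tibble).
#' @param protein A protein sequence (or one-row proteome tibble).
#' @param params A [match_params()] object.
#' @return A hit tibble with columns `sequence`, `protein_id`, `p_start`,
#'   `p_end` (1-based inclusive protein coordinates), `pep_start`,
#'   `matched_substring` (the protein-side residues of the window) and
#'   `score` (window length in exact mode).
#' @examples
#' find_hits("VPWSKPW", "MTDAAPWSKVTQ",
#'           match_params(min_exact_window = 4))
#' @export
find_hits <- function(peptide, protein, params = match_params()) {
  pep <- if (is.data.frame(peptide)) peptide$sequence[1] else peptide
  if (is.data.frame(protein)) {
    prot <- protein$sequence[1]; prot_id <- protein$protein_id[1]
  } else {
    prot <- protein; prot_id <- "protein"
  }
  pep <- validate_sequences(pep, "peptide", allow_x = TRUE)
  prot <- validate_sequences(prot, "protein", allow_x = TRUE)
  if (nchar(pep) < min_peptide_length(params))
    abort(sprintf("Peptide '%s' (length %d) is shorter than the minimum matchable length %d; filter such peptides before searching.",
                  pep, nchar(pep), min_peptide_length(params)))
  raw <- search_core(pep, prot, params)
  tibble::tibble(
    sequence = rep(pep, nrow(raw)),
    protein_id = rep(prot_id, nrow(raw)),
    p_start = raw$p_start, p_end = raw$p_end, pep_start = raw$pep_start,
    matched_substring = substr(rep(prot, nrow(raw)), raw$p_start, raw$p_end),
    score = raw$score
  )
}

#' Search peptide panels against a protein database
#'
#' Runs the matcher for every (peptide, protein) pair; peptides shorter than
#' the minimum matchable length are skipped with a message (they are likewise
#' excluded from the panel size `n` by [rank_candidates()]). Hit order is
#' deterministic: panel order, then proteome order, then position.
#'
#' @param panels Panel tibble ([read_panels()]); one or many panels.
#' @param proteome Proteome tibble ([read_proteome()]).
#' @param params A [match_params()] object, shared verbatim with the null
#'   search (see [estimate_null()]).
#' @return A hit tibble with columns `panel_id`, `sequence`, `protein_id`,
#'   `p_start`, `p_end`, `pep_start`, `matched_substring`, `score`, carrying
#'   `params` as an attribute.
#' @export
search_panels <- function(panels, proteome, params = match_params()) {
  if (nrow(proteome) == 0) abort("Proteome is empty: nothing to search against.")
  wmin <- min_peptide_length(params)
  short <- nchar(panels$sequence) < wmin
  if (any(short)) {
    inform(sprintf("Skipping %d peptide(s) shorter than %d aa: %s",
                   sum(short), wmin,
                   paste(panels$sequence[short], collapse = ", ")))
    panels <- panels[!short, , drop = FALSE]
  }
  if (nrow(panels) == 0) {
    out <- tibble::tibble(panel_id = character(), sequence = character(),
                          protein_id = character(), p_start = integer(),
                          p_end = integer(), pep_start = integer(),
                          matched_substring = character(), score = integer())
    attr(out, "match_params") <- params
    return(out)
  }
  raw <- search_core(panels$sequence, proteome$sequence, params)
  out <- tibble::tibble(
    panel_id = panels$panel_id[raw$pep_i],
    sequence = panels$sequence[raw$pep_i],
    protein_id = proteome$protein_id[raw$prot_i],
    p_start = raw$p_start, p_end = raw$p_end, pep_start = raw$pep_start,
    matched_substring = substr(proteome$sequence[raw$prot_i],
                               raw$p_start, raw$p_end),
    score = raw$score
  )
  attr(out, "match_params") <- params
  out
}

#' Deduplicate hits to one best hit per (panel, peptide, protein)
#'
#' The candidate statistics count matching peptides, not matching sites: a
#' peptide matching one protein at several positions is one match. The
#' retained hit is the best one — highest score, then smallest protein start,
#' then smallest peptide offset.
#'
#' @param hits Hit tibble from [search_panels()] or [external_to_hits()].
#' @return The deduplicated hit tibble (same columns), `match_params`
#'   attribute preserved.
#' @export
dedupe_hits <- function(hits) {
  params <- attr(hits, "match_params")
  if (nrow(hits) == 0) return(hits)
  key_panel <- if ("panel_id" %in% names(hits)) hits$panel_id else ""
  ord <- order(key_panel, hits$sequence, hits$protein_id,
               -ifelse(is.na(hits$score), -1L, hits$score),
               hits$p_start, hits$pep_start)
  out <- hits[ord, , drop = FALSE]
  keep <- !duplicated(paste(key_panel[ord], out$sequence, out$protein_id,
                            sep = "\r"))
  out <- out[keep, , drop = FALSE]
  attr(out, "match_params") <- params
  out
}
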
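#' Reverse peptides ("spelt backwards" decoys)
#'
#' Character-reverses each sequence. Reversed peptides have the same length
#' and residue composition as the originals, so searching them against the
#' same database under the same matcher parameters measures the chance-match
#' rate while destroying any genuine epitope signal.
#'
#' @param sequence Character vector of peptide sequences.
#' @return The reversed sequences.
#' @examples
#' reverse_peptide(c("KYRWYK", "TGVRGQRISQ"))
#' @export
reverse_peptide <- function(sequence) {
  stringi::stri_reverse(sequence)
}

#' Construct a null estimate
#'
#' Builds the chance-match frequency object consumed by [rank_candidates()].
#' Normally produced by [estimate_null()]; the constructor is exported so a
#' null computed with an external search engine (on the reversed peptides,
#' with the same engine and parameters as the forward search) can be supplied
#' alongside externally imported match tables.
#'
#' @param f_mean Mean chance-match frequency, per peptide per 1000 aa.
#' @param f_sd Dispersion (standard deviation of per-protein frequencies).
#' @param n_peptides_used Number of (unique) reversed peptides searched.
#' @param proteins_used Tibble of the proteins behind the estimate
#'   (`protein_id`, `matches`, `length_aa`, `f_per_1000aa`).
#' @param min_matches_threshold The match-count threshold used.
#' @param params The [match_params()] the reversed search used, or `NULL`
#'   for an externally produced null.
#' @return A `null_estimate` object.
#' @export
null_estimate <- function(f_mean, f_sd, n_peptides_used,
                          proteins_used = tibble::tibble(
                            protein_id = character(), matches = integer(),
                            length_aa = integer(), f_per_1000aa = double()),
                          min_matches_threshold = 4L, params = NULL) {
  if (is.na(f_mean) || f_mean < 0) abort("f_mean must be >= 0.")
  if (is.na(f_sd) || f_sd < 0) abort("f_sd must be >= 0.")
  structure(list(f_mean = f_mean, f_sd = f_sd,
                 n_peptides_used = as.integer(n_peptides_used),
                 proteins_used = tibble::as_tibble(proteins_used),
                 min_matches_threshold = as.integer(min_matches_threshold),
                 params = params),
            class = "null_estimate")
}

#' Estimate the chance-match frequency from reversed peptides
#'
#' All panel peptides are reversed and searched against the proteome with the
#' *same* matcher parameters as the forward analysis. Per protein, the number
#' of distinct reversed peptides matching it (M) is counted; for every
#' protein with `M >= min_matches_threshold` the length-normalized frequency
#' `f_i = M / (N * L / 1000)` (matches per peptide per 1000 aa, with N the
#' number of peptides and L the protein length) is computed, and the estimate
#' is the mean and standard deviation of those per-protein frequencies.
#'
#' Thresholding on overrepresented proteins conditions the estimate upward,
#' which is conservative: an inflated null makes candidate significance
#' harder to reach. `min_matches_threshold = 0` gives the unconditioned
#' estimator over all proteins (matches of 0 included), which is unbiased and
#' is what calibration against a closed-form chance rate should use.
#'
#' @param panels Panel tibble; all peptides of all included panels are used.
#' @param proteome Proteome tibble.
#' @param params The forward analysis's [match_params()] (the same object
#'   must be passed to [search_panels()]; [rank_candidates()] enforces the
#'   identity).
#' @param min_matches_threshold Keep proteins with at least this many
#'   distinct reversed-peptide matches (default 4). With 0, every protein
#'   contributes.
#' @return A [null_estimate()] object.
#' @export
estimate_null <- function(panels, proteome, params = match_params(),
                          min_matches_threshold = 4L) {
  min_matches_threshold <- as.integer(min_matches_threshold)
  wmin <- min_peptide_length(params)
  peps <- unique(panels$sequence[nchar(panels$sequence) >= wmin])
  N <- length(peps)
  if (N < 10)
    abort(sprintf("Only %d unique matchable peptides: at least 10 are required for a null estimate.", N))
  if (N < 30)
    warn(sprintf("Null estimated from only %d peptides; the chance-match frequency will be noisy.", N))
  rev_pep <- unique(reverse_peptide(peps))
  rev_panels <- tibble::tibble(panel_id = "reversed-null", patient_id = "null",
                               antibody_class = "null", sequence = rev_pep,
                               copy_number = 1L, source_label = "reversed")
  hits <- dedupe_hits(search_panels(rev_panels, proteome, params))
  m_tbl <- hits %>%
    dplyr::count(.data$protein_id, name = "matches")
  prot <- proteome %>%
    dplyr::select("protein_id", "length_aa") %>%
    dplyr::left_join(m_tbl, by = "protein_id") %>%
    dplyr::mutate(matches = as.integer(dplyr::coalesce(.data$matches, 0L)),
                  f_per_1000aa = .data$matches / (N * .data$length_aa / 1000))
  used <- prot %>% dplyr::filter(.data$matches >= min_matches_threshold)
  if (nrow(used) == 0)
    abort(sprintf(paste0(
      "No protein reached %d reversed-peptide matches; the chance-match ",
      "frequency cannot be estimated. Lower min_matches_threshold (0 gives the ",
      "unconditioned estimate over all proteins) or search a larger proteome."),
      min_matches_threshold))
  f_sd <- if (nrow(used) > 1) stats::sd(used$f_per_1000aa) else 0
  null_estimate(f_mean = mean(used$f_per_1000aa), f_sd = f_sd,
                n_peptides_used = N, proteins_used = used,
                min_matches_threshold = min_matches_threshold, params = params)
}

#' @export
print.null_estimate <- function(x, ...) {
  cat(sprintf(
    "<null_estimate> f = %.4g +/- %.4g matches per peptide per 1000 aa\n  (%d reversed peptides; %d protein(s) with >= %d matches)\n",
    x$f_mean, x$f_sd, x$n_peptides_used, nrow(x$proteins_used),
    x$min_matches_threshold))
  invisible(x)
}

#' Chance-match probability for a protein of a given length
#'
#' The probability that one peptide matches a protein by chance is taken as
#' directly proportional to the protein length: `p0 = min(1, f * L / 1000)`,
#' with `f` the chance-match frequency per peptide per 1000 aa.
#'
#' @param f Chance-match frequency (scalar or vector), per peptide per
#'   1000 aa.
#' @param L Protein length(s) in amino acids.
#' @return The capped chance probability, vectorized over `f` and `L`.
#' @examples
#' chance_prob(0.02, 403)   # 0.00806
#' chance_prob(0.02, 1000)  # 0.02, the definition at 1000 aa
#' @export
chance_prob <- function(f, L) {
  if (any(is.na(f)) || any(f < 0)) abort("f must be >= 0.")
  if (any(is.na(L)) || any(L < 1)) abort("L must be >= 1 amino acid.")
  pmin(1, f * L / 1000)
}

#' @rdname null_estimate
#' @param x A `null_estimate` object.
#' @param ... Unused.
#' @method tidy null_estimate
#' @export
tidy.null_estimate <- function(x, ...) {
  x$proteins_used
}

#' @rdname null_estimate
#' @method glance null_estimate
#' @export
glance.null_estimate <- function(x, ...) {
  tibble::tibble(f_mean = x$f_mean, f_sd = x$f_sd,
                 n_peptides_used = x$n_peptides_used,
                 n_proteins_used = nrow(x$proteins_used),
                 min_matches_threshold = x$min_matches_threshold)
}
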
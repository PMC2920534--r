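#' Extract conserved motifs shared among a panel's peptides
#'
#' Enumerates every ungapped pattern of length `min_len` to `max_len`, with up
#' to `max_wildcards` wildcard positions (never at either end), that occurs in
#' at least two *distinct* peptide sequences of a panel, and reports the
#' maximal such patterns: a pattern is dropped when another reported pattern
#' with the identical member set contains it (so `SPTH` is reported once, not
#' alongside `SPT` or `SPxH`). Clonal identity is not a motif — identical
#' inserts contribute one member.
#'
#' @param panels Panel tibble; may hold several panels (processed per panel).
#' @param min_len,max_len Pattern length bounds (defaults 4 and 6; serum
#'   antibody-recognized motifs are usually four or five residues).
#' @param max_wildcards Wildcard budget per pattern (default 1; wildcards are
#'   written `x` and match any residue).
#' @return A tibble with columns `panel_id`, `consensus`, `motif_length`,
#'   `n_members`, `phage_support` (summed clonal copy numbers of the
#'   members) and a `members` list-column, sorted by member count, phage
#'   support (both decreasing) and consensus. Panels with fewer than two
#'   records yield no rows.
#' @examples
#' pan <- as_peptide_panels(tibble::tibble(
#'   patient_id = "C", antibody_class = "IgG",
#'   sequence = c("KENGRSPTHS", "SPTHP", "GRSNKSG", "GRRNKSG")))
#' extract_shared_motifs(pan, max_len = 7)
#' @export
extract_shared_motifs <- function(panels, min_len = 4L, max_len = 6L,
                                  max_wildcards = 1L) {
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  if (min_len < 4 || max_len > 10 || min_len > max_len)
    abort("Motif lengths must satisfy 4 <= min_len <= max_len <= 10.")
  panels %>%
    dplyr::group_by(.data$panel_id) %>%
    dplyr::group_map(~ motifs_one_panel(.x, .y$panel_id, min_len, max_len,
                                        max_wildcards)) %>%
    dplyr::bind_rows()
}

motifs_one_panel <- function(panel, panel_id, min_len, max_len, max_wildcards) {
  empty <- tibble::tibble(panel_id = character(), consensus = character(),
                          motif_length = integer(), n_members = integer(),
                          phage_support = integer(), members = list())
  seqs <- unique(panel$sequence)
  if (length(seqs) < 2) return(empty)
  copies <- vapply(seqs, function(s) sum(panel$copy_number[panel$sequence == s]),
                   integer(1))

  pats <- unique(unlist(lapply(seqs, enumerate_patterns,
                               min_len = min_len, max_len = max_len,
                               max_wildcards = max_wildcards)))
  if (length(pats) == 0) return(empty)
  member_sets <- lapply(pats, function(p) seqs[pattern_matches(p, seqs)])
  n_mem <- lengths(member_sets)
  keep <- n_mem >= 2
  pats <- pats[keep]; member_sets <- member_sets[keep]
  if (length(pats) == 0) return(empty)

  # maximality within identical member sets: drop patterns contained in
  # another pattern of the same set
  keys <- vapply(member_sets, function(m) paste(sort(m), collapse = "\r"),
                 character(1))
  keep <- rep(TRUE, length(pats))
  for (key in unique(keys)) {
    idx <- which(keys == key)
    if (length(idx) < 2) next
    for (i in idx) {
      for (j in idx) {
        if (i != j && pattern_contained(pats[i], pats[j])) { keep[i] <- FALSE; break }
      }
    }
  }
  pats <- pats[keep]; member_sets <- member_sets[keep]

  out <- tibble::tibble(
    panel_id = panel_id,
    consensus = pats,
    motif_length = nchar(pats),
    n_members = lengths(member_sets),
    phage_support = vapply(member_sets, function(m) sum(copies[m]), integer(1)),
    members = lapply(member_sets, function(m) m[order(m)])
  )
  out[order(-out$n_members, -out$phage_support, out$consensus), ]
}

# All wildcard patterns derivable from substrings of one sequence.
enumerate_patterns <- function(seq, min_len, max_len, max_wildcards) {
  n <- nchar(seq)
  out <- character(0)
  for (len in min_len:min(max_len, n)) {
    for (start in seq_len(n - len + 1)) {
      sub <- substr(seq, start, start + len - 1)
      out <- c(out, sub)
      if (max_wildcards > 0 && len >= 3) {
        interior <- 2:(len - 1)
        for (w in seq_len(min(max_wildcards, length(interior)))) {
          combos <- utils::combn(interior, w, simplify = FALSE)
          for (pos in combos) {
            v <- strsplit(sub, "")[[1]]
            v[pos] <- "x"
            out <- c(out, paste(v, collapse = ""))
          }
        }
      }
    }
  }
  unique(out)
}

pattern_regex <- function(pattern) {
  gsub("x", ".", pattern, fixed = TRUE)
}

pattern_matches <- function(pattern, seqs) {
  stringr::str_detect(seqs, pattern_regex(pattern))
}

# TRUE iff pattern `a` occurs as a sub-window of pattern `b`, treating a
# wildcard in `a` as compatible with anything.
pattern_contained <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (la > lb) return(FALSE)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  for (off in 0:(lb - la)) {
    if (all(av == "x" | av == bv[(off + 1):(off + la)])) return(TRUE)
  }
  FALSE
}

#' Scan a panel for a wildcard pattern
#'
#' Counts the phage particles (summed clonal copy numbers) whose insert
#' contains the pattern, e.g. `"KxxGHH"`. Wildcards `x`/`X` match any
#' residue; leading and trailing wildcards are trimmed before matching, and
#' the trimmed pattern must reach `min_len`.
#'
#' @param panels Panel tibble; may hold several panels (scanned per panel).
#' @param pattern Wildcard pattern string.
#' @param min_len Minimum trimmed pattern length (default 4, floor 3).
#' @return A tibble with one row per panel: `panel_id`, `pattern`,
#'   `n_members` (distinct matching sequences), `n_phage` (their summed
#'   copies) and a `members` list-column.
#' @export
scan_pattern <- function(panels, pattern, min_len = 4L) {
  if (length(pattern) != 1 || is.na(pattern) || nchar(pattern) == 0)
    abort("Pattern must be a single non-empty string.")
  min_len <- max(3L, as.integer(min_len))
  norm <- toupper(pattern)
  norm <- gsub("^X+|X+$", "", norm)
  norm <- gsub("X", "x", norm)
  if (nchar(norm) < min_len)
    abort(sprintf("Pattern '%s' normalizes to '%s' (length %d), below the minimum length %d.",
                  pattern, norm, nchar(norm), min_len))
  letters_only <- gsub("x", "", norm, fixed = TRUE)
  validate_sequences(letters_only, "pattern")
  panels %>%
    dplyr::group_by(.data$panel_id) %>%
    dplyr::summarise(
      pattern = norm,
      n_members = dplyr::n_distinct(.data$sequence[pattern_matches(norm, .data$sequence)]),
      n_phage = sum(.data$copy_number[pattern_matches(norm, .data$sequence)]),
      members = list(sort(unique(.data$sequence[pattern_matches(norm, .data$sequence)]))),
      .groups = "drop"
    )
}

#' Clonality summary of peptide panels
#'
#' @param panels Panel tibble (non-empty).
#' @return One row per panel: `panel_id`, `n_unique` (distinct inserts),
#'   `n_phage` (total phage particles, i.e. summed copy numbers),
#'   `top_sequence` (highest copy number, ties broken lexicographically) and
#'   `top_count`.
#' @examples
#' clone_summary(table1_panels())
#' @export
clone_summary <- function(panels) {
  if (nrow(panels) == 0) abort("Empty panel: nothing to summarise.")
  panels %>%
    dplyr::group_by(.data$panel_id) %>%
    dplyr::summarise(
      n_unique = dplyr::n(),
      n_phage = sum(.data$copy_number),
      top_sequence = .data$sequence[order(-.data$copy_number, .data$sequence)][1],
      top_count = max(.data$copy_number),
      .groups = "drop"
    )
}
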
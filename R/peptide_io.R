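#' Read biopanning peptide panels
#'
#' Reads per-patient, per-antibody-class peptide panels from a TSV file with
#' header columns `patient_id`, `antibody_class`, `sequence` and (optionally)
#' `copy_number`, or from a FASTA file whose headers have the form
#' `patientID|class|copyN`. Duplicate sequences within a panel are merged by
#' summing their clonal copy numbers; record order is the input order of first
#' occurrence. Sequences are validated against the 20-letter amino-acid
#' alphabet and must be 4-50 residues long.
#'
#' @param path Path to a TSV (default) or FASTA file.
#' @param format `"tsv"` or `"fasta"`; guessed from the file extension when
#'   `NULL`.
#' @param allow_x Admit `X` as a never-matching residue (off by default; the
#'   match statistics assume a fixed 20-letter alphabet).
#' @return A tibble with one row per unique peptide: `panel_id`
#'   (`"patient/class"`), `patient_id`, `antibody_class`, `sequence`,
#'   `copy_number`, `source_label`.
#' @seealso [table1_panels()] for the worked reference fixture,
#'   [write_panels()] for the inverse operation.
#' @export
read_panels <- function(path, format = NULL, allow_x = FALSE) {
  if (!file.exists(path)) abort(paste0("Panel file not found: ", path))
  format <- format %||%
    (if (grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE)) "fasta" else "tsv")
  if (format == "fasta") {
    seqs <- read_fasta_checked(path, what = "peptide")
    parts <- stringr::str_split_fixed(seqs$protein_id, stringr::fixed("|"), 3)
    bad <- which(parts[, 1] == "" | parts[, 2] == "")
    if (length(bad) > 0)
      abort(sprintf("Malformed FASTA panel header '%s': expected 'patientID|class|copyN'.",
                    seqs$protein_id[bad[1]]), class = "mimoscan_parse_error")
    df <- tibble::tibble(
      patient_id = parts[, 1],
      antibody_class = parts[, 2],
      sequence = seqs$sequence,
      copy_number = suppressWarnings(as.integer(parts[, 3])),
      source_label = path
    )
    df$copy_number[is.na(df$copy_number)] <- 1L
  } else {
    raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    need <- c("patient_id", "antibody_class", "sequence")
    miss <- setdiff(need, names(raw))
    if (length(miss) > 0)
      abort(paste0("Panel TSV is missing required column(s): ",
                   paste(miss, collapse = ", ")), class = "mimoscan_parse_error")
    line <- seq_len(nrow(raw)) + 1L  # header is line 1
    bad <- which(is.na(raw$patient_id) | is.na(raw$antibody_class) | is.na(raw$sequence))
    if (length(bad) > 0)
      abort(sprintf("Malformed panel row at line %d: missing patient_id, antibody_class or sequence.",
                    line[bad[1]]), class = "mimoscan_parse_error")
    cn <- if ("copy_number" %in% names(raw)) raw$copy_number else rep("1", nrow(raw))
    cn[is.na(cn) | cn == ""] <- "1"
    cni <- suppressWarnings(as.integer(cn))
    bad <- which(is.na(cni) | cni < 1)
    if (length(bad) > 0)
      abort(sprintf("Malformed copy_number '%s' at line %d: must be a positive integer.",
                    cn[bad[1]], line[bad[1]]), class = "mimoscan_parse_error")
    df <- tibble::tibble(
      patient_id = raw$patient_id,
      antibody_class = raw$antibody_class,
      sequence = validate_sequences(raw$sequence, "peptide", allow_x, line),
      copy_number = cni,
      source_label = if ("source_label" %in% names(raw)) raw$source_label else path
    )
  }
  as_peptide_panels(df, allow_x = allow_x)
}

#' Validate and normalize a peptide-panel data frame
#'
#' Coerces any data frame with `patient_id`, `antibody_class`, `sequence` and
#' optionally `copy_number` columns into the canonical panel tibble used by
#' every downstream function: sequences uppercased and validated (4-50
#' residues over the 20-letter alphabet), duplicates within a panel merged
#' into `copy_number`, a `panel_id` of the form `"patient/class"` added.
#'
#' @param df A data frame of peptide records.
#' @inheritParams read_panels
#' @return A validated panel tibble (see [read_panels()]).
#' @export
as_peptide_panels <- function(df, allow_x = FALSE) {
  df <- tibble::as_tibble(df)
  if (!"copy_number" %in% names(df)) df$copy_number <- 1L
  if (!"source_label" %in% names(df)) df$source_label <- NA_character_
  df$copy_number <- as.integer(df$copy_number)
  if (any(is.na(df$copy_number) | df$copy_number < 1))
    abort("copy_number must be a positive integer (>= 1).")
  df$sequence <- validate_sequences(df$sequence, "peptide", allow_x)
  nc <- nchar(df$sequence)
  if (any(nc < 4 | nc > 50))
    abort(sprintf("Peptide '%s' has length %d: panel peptides must be 4-50 aa.",
                  df$sequence[which(nc < 4 | nc > 50)[1]],
                  nc[which(nc < 4 | nc > 50)[1]]),
          class = "mimoscan_parse_error")
  df %>%
    dplyr::mutate(panel_id = paste(.data$patient_id, .data$antibody_class, sep = "/"),
                  .row = dplyr::row_number()) %>%
    dplyr::group_by(.data$panel_id, .data$patient_id, .data$antibody_class,
                    .data$sequence) %>%
    dplyr::summarise(copy_number = sum(.data$copy_number),
                     source_label = dplyr::first(.data$source_label),
                     .row = min(.data$.row), .groups = "drop") %>%
    dplyr::arrange(.data$.row) %>%
    dplyr::select("panel_id", "patient_id", "antibody_class", "sequence",
                  "copy_number", "source_label")
}

#' Write peptide panels to TSV
#'
#' @param panels A panel tibble (see [read_panels()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_panels <- function(panels, path) {
  readr::write_tsv(panels[, c("patient_id", "antibody_class", "sequence",
                              "copy_number", "source_label")], path,
                   progress = FALSE)
  invisible(path)
}

# Shared FASTA reader: uppercases, validates ids, errors on empty files and
# duplicate ids.
read_fasta_checked <- function(path, what = "protein") {
  ss <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) abort(paste0("Cannot read FASTA file ", path, ": ",
                                                  conditionMessage(e))))
  if (length(ss) == 0) abort(paste0("FASTA file is empty: ", path))
  headers <- names(ss)
  ids <- stringr::str_split_fixed(headers, "\\s+", 2)[, 1]
  desc <- stringr::str_split_fixed(headers, "\\s+", 2)[, 2]
  if (anyDuplicated(ids) > 0) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("Duplicate ", what, " id(s) in ", path, ": ",
                 paste(dup, collapse = ", ")), class = "mimoscan_parse_error")
  }
  tibble::tibble(protein_id = unname(ids), description = unname(desc),
                 sequence = unname(toupper(as.character(ss))))
}

#' Read a protein database from FASTA
#'
#' The first whitespace-delimited token of each header is the protein id;
#' the remainder is kept as the description. Sequences are uppercased and
#' their lengths recorded.
#'
#' @param path Path to a FASTA file.
#' @param allow_x Admit `X` as a never-matching residue.
#' @return A tibble with columns `protein_id`, `description`, `sequence`,
#'   `length_aa`, in file order.
#' @export
read_proteome <- function(path, allow_x = FALSE) {
  df <- read_fasta_checked(path, what = "protein")
  df$sequence <- validate_sequences(df$sequence, "protein", allow_x)
  df$length_aa <- nchar(df$sequence)
  df
}

#' Write a protein database to FASTA
#'
#' @param proteome A proteome tibble (see [read_proteome()]).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(proteome, path) {
  ss <- Biostrings::AAStringSet(proteome$sequence)
  names(ss) <- ifelse(is.na(proteome$description) | proteome$description == "",
                      proteome$protein_id,
                      paste(proteome$protein_id, proteome$description))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read externally produced match tables (BLAST outfmt-6 dialect)
#'
#' Accepts 12-column tabular output in the classic BLAST `-outfmt 6` layout;
#' columns 1, 2, 9 and 10 are used as `peptide_id`, `protein_id`,
#' `align_start` and `align_end` (1-based, inclusive, protein coordinates).
#'
#' @param path Path to the tabular file. An empty file yields an empty tibble.
#' @return A tibble with columns `peptide_id`, `protein_id`, `align_start`,
#'   `align_end`.
#' @seealso [external_to_hits()] to convert the rows into the hit-table layout
#'   used downstream.
#' @export
read_external_matches <- function(path) {
  if (!file.exists(path)) abort(paste0("Match file not found: ", path))
  empty <- tibble::tibble(peptide_id = character(), protein_id = character(),
                          align_start = integer(), align_end = integer())
  if (file.size(path) == 0) return(empty)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (nrow(raw) == 0) return(empty)
  if (ncol(raw) < 10)
    abort("External match table must have at least 10 tab-separated columns (BLAST outfmt 6).",
          class = "mimoscan_parse_error")
  out <- tibble::tibble(
    peptide_id = raw[[1]],
    protein_id = raw[[2]],
    align_start = suppressWarnings(as.integer(raw[[9]])),
    align_end = suppressWarnings(as.integer(raw[[10]]))
  )
  bad <- which(is.na(out$align_start) | is.na(out$align_end) |
                 out$align_start < 1 | out$align_start > out$align_end)
  if (length(bad) > 0)
    abort(sprintf("Invalid alignment coordinates (start %s, end %s) at row %d.",
                  raw[[9]][bad[1]], raw[[10]][bad[1]], bad[1]),
          class = "mimoscan_parse_error")
  out
}

#' Convert external match rows into the internal hit-table layout
#'
#' Resolves each `peptide_id` either as `"panel_id|sequence"` (the dialect
#' [write_hits()] emits) or as a bare peptide sequence looked up across the
#' supplied panels, and extracts the matched protein-side substring when the
#' proteome is available.
#'
#' @param matches Tibble from [read_external_matches()].
#' @param panels Panel tibble.
#' @param proteome Optional proteome tibble; when supplied, hits to unknown
#'   proteins are an error and `matched_substring` is filled in.
#' @return A hit tibble as produced by [search_panels()] (score `NA` for
#'   external rows).
#' @export
external_to_hits <- function(matches, panels, proteome = NULL) {
  if (nrow(matches) == 0) {
    return(tibble::tibble(panel_id = character(), sequence = character(),
                          protein_id = character(), p_start = integer(),
                          p_end = integer(), pep_start = integer(),
                          matched_substring = character(), score = integer()))
  }
  has_bar <- stringr::str_detect(matches$peptide_id, stringr::fixed("|"))
  panel_id <- ifelse(has_bar,
                     stringr::str_extract(matches$peptide_id, "^.*(?=\\|)"),
                     NA_character_)
  sequence <- ifelse(has_bar,
                     stringr::str_extract(matches$peptide_id, "(?<=\\|)[^|]*$"),
                     matches$peptide_id)
  if (any(!has_bar)) {
    lookup <- panels[, c("panel_id", "sequence")]
    idx <- match(sequence[!has_bar], lookup$sequence)
    if (anyNA(idx))
      abort(sprintf("peptide_id '%s' is neither 'panel|sequence' nor a sequence present in the panels.",
                    sequence[!has_bar][which(is.na(idx))[1]]))
    panel_id[!has_bar] <- lookup$panel_id[idx]
  }
  out <- tibble::tibble(
    panel_id = panel_id, sequence = toupper(sequence),
    protein_id = matches$protein_id,
    p_start = matches$align_start, p_end = matches$align_end,
    pep_start = NA_integer_, matched_substring = NA_character_,
    score = NA_integer_
  )
  if (!is.null(proteome)) {
    idx <- match(out$protein_id, proteome$protein_id)
    if (anyNA(idx))
      abort(paste0("External matches reference protein id(s) absent from the proteome: ",
                   paste(unique(out$protein_id[is.na(idx)]), collapse = ", ")))
    if (any(out$p_end > proteome$length_aa[idx]))
      abort("External match coordinates extend past the protein end.")
    out$matched_substring <- substr(proteome$sequence[idx], out$p_start, out$p_end)
  }
  out
}

#' Write a hit table in the BLAST outfmt-6 dialect
#'
#' Built-in and imported matches are interchangeable downstream: the query id
#' is written as `"panel_id|sequence"`, percent identity and bitscore carry
#' the matcher's window identity and score.
#'
#' @param hits Hit tibble from [search_panels()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  n <- nrow(hits)
  wlen <- hits$p_end - hits$p_start + 1L
  df <- data.frame(
    qseqid = paste(hits$panel_id, hits$sequence, sep = "|"),
    sseqid = hits$protein_id,
    pident = format_report_num(100 * ifelse(is.na(hits$score) | hits$score == wlen,
                                            1, pmin(1, hits$score / pmax(wlen, 1)))),
    length = wlen,
    mismatch = 0L, gapopen = 0L,
    qstart = hits$pep_start, qend = hits$pep_start + wlen - 1L,
    sstart = hits$p_start, send = hits$p_end,
    evalue = 0, bitscore = ifelse(is.na(hits$score), 0L, hits$score)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Fixed float formatting contract for reports: 6 significant digits,
# scientific notation below 1e-4, so identical inputs give byte-identical
# files.
format_report_num <- function(x) {
  out <- character(length(x))
  out[is.na(x)] <- "NA"
  ok <- !is.na(x)
  sci <- ok & abs(x) < 1e-4 & x != 0
  out[ok & !sci] <- formatC(signif(x[ok & !sci], 6), format = "fg",
                            digits = 6, flag = "#")
  out[sci] <- formatC(x[sci], format = "e", digits = 5)
  # trim trailing '.' left by formatC on integers printed with flag '#'
  out <- sub("\\.$", "", out)
  sub("(\\.[0-9]*?)0+$", "\\1", out) -> out
  sub("\\.$", "", out)
}

#' Write a ranked candidate report (TSV + JSON)
#'
#' The TSV carries the per-candidate summary (columns `panel_id`,
#' `protein_id`, `length_aa`, `n`, `k`, `k_eff`, `p_binomial`, `p_fisher`,
#' `flags`, plus motif/contrast detail); the JSON mirrors it at full
#' precision, optionally with per-hit detail, and is the exact round-trip
#' medium. Output is byte-identical for identical input: rows are written in
#' their (stable) rank order and floats use a fixed 6-significant-digit
#' format.
#'
#' @param results Candidate tibble from [rank_candidates()].
#' @param path Output TSV path; the JSON is written alongside with a `.json`
#'   extension unless `json_path` is given.
#' @param json_path Optional explicit JSON path.
#' @param hits Optional hit tibble; when supplied, each JSON record carries
#'   its supporting hits.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, json_path = NULL, hits = NULL) {
  json_path <- json_path %||% sub("\\.tsv$", ".json", path)
  if (identical(json_path, path)) json_path <- paste0(path, ".json")
  cols <- c("panel_id", "protein_id", "length_aa", "n", "k", "k_eff",
            "p_binomial", "p_fisher", "flags", "shared_motif",
            "other_matches", "other_total", "q_value")
  res <- tibble::as_tibble(results)
  for (cc in setdiff(cols, names(res))) res[[cc]] <- NA
  res <- res[, cols]
  out <- res
  for (cc in c("p_binomial", "p_fisher", "q_value"))
    out[[cc]] <- format_report_num(res[[cc]])
  con <- tryCatch(file(path, "wb"), error = function(e)
    abort(paste0("Cannot write report to ", path, ": ", conditionMessage(e))))
  on.exit(close(con), add = TRUE)
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(out) > 0) {
    body <- do.call(paste, c(lapply(out, function(v) {
      v <- as.character(v); v[is.na(v)] <- "NA"; v
    }), sep = "\t"))
    writeLines(body, con)
  }
  payload <- list(candidates = res)
  if (!is.null(hits)) {
    payload$hits <- hits %>%
      dplyr::semi_join(res, by = c("panel_id", "protein_id"))
  }
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a candidate report
#'
#' @param path Path to the TSV written by [write_report()] (or its JSON
#'   sibling; `.json` paths are parsed at full precision).
#' @return A candidate tibble.
#' @export
read_report <- function(path) {
  if (grepl("\\.json$", path)) {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- tibble::as_tibble(payload$candidates)
    if (nrow(df) == 0) return(empty_report())
    for (cc in c("shared_motif", "flags")) df[[cc]] <- as.character(df[[cc]])
    return(df)
  }
  df <- readr::read_tsv(path, col_types = readr::cols(
    panel_id = readr::col_character(), protein_id = readr::col_character(),
    length_aa = readr::col_integer(), n = readr::col_integer(),
    k = readr::col_integer(), k_eff = readr::col_integer(),
    p_binomial = readr::col_double(), p_fisher = readr::col_double(),
    flags = readr::col_character(), shared_motif = readr::col_character(),
    other_matches = readr::col_integer(), other_total = readr::col_integer(),
    q_value = readr::col_double()), na = "NA", progress = FALSE)
  tibble::as_tibble(df)
}

empty_report <- function() {
  tibble::tibble(panel_id = character(), protein_id = character(),
                 length_aa = integer(), n = integer(), k = integer(),
                 k_eff = integer(), p_binomial = double(), p_fisher = double(),
                 flags = character(), shared_motif = character(),
                 other_matches = integer(), other_total = integer(),
                 q_value = double())
}
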
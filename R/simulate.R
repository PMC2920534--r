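#' Specify one synthetic biopanning panel
#'
#' A panel emulates the structure of real biopanning output: clonally
#' expanded inserts (geometric copy numbers), an optional family of peptides
#' sharing a short motif that also occurs in a database protein (the
#' shared-motif trap that motif collapse must defuse), optional carrier
#' peptides embedding epitopes of a planted antigen, and random background
#' singletons.
#'
#' By default each epitope carrier receives its *own* epitope site of the
#' planted protein (distinct, non-overlapping sites): different peptides
#' mimicking different sequential epitopes of one antigen is what makes
#' multiple matches independent evidence. With `shared_epitope = TRUE` all
#' carriers embed one common site instead — a variant whose matches the
#' motif-collapse rule then correctly counts once.
#'
#' @param patient_id,antibody_class Panel identity.
#' @param n_unique Number of distinct peptides.
#' @param peptide_length_range Inclusive length bounds for random peptides
#'   (default 7-12 aa, within the 5-16 aa range of mixed phage-display
#'   libraries).
#' @param copy_geom_prob Success probability of the geometric copy-number law
#'   (default 0.5, i.e. mean 2 copies per insert).
#' @param n_epitope_peptides Carriers embedding planted epitopes (default 0).
#' @param planted_protein Index of the planted antigen in the generated
#'   proteome (required when `n_epitope_peptides > 0`).
#' @param epitope_length Epitope length in residues (default 6; must fit the
#'   shortest peptide).
#' @param epitope_mutations Substitutions applied to each carrier's epitope
#'   copy (default 0; the matcher is ungapped, so only substitutions are
#'   modeled).
#' @param shared_epitope All carriers share one epitope site (default FALSE).
#' @param motif_family_size Size of the shared-motif family (default 0 = no
#'   family; otherwise >= 2 peptides sharing a random 4-mer taken from
#'   `motif_protein`).
#' @param motif_protein Index of the database protein the family 4-mer is
#'   taken from.
#' @return A `panel_spec` list.
#' @export
panel_spec <- function(patient_id, antibody_class = "IgG", n_unique = 10L,
                       peptide_length_range = c(7L, 12L),
                       copy_geom_prob = 0.5,
                       n_epitope_peptides = 0L, planted_protein = NA_integer_,
                       epitope_length = 6L, epitope_mutations = 0L,
                       shared_epitope = FALSE,
                       motif_family_size = 0L, motif_protein = NA_integer_) {
  spec <- list(patient_id = patient_id, antibody_class = antibody_class,
               n_unique = as.integer(n_unique),
               peptide_length_range = as.integer(peptide_length_range),
               copy_geom_prob = copy_geom_prob,
               n_epitope_peptides = as.integer(n_epitope_peptides),
               planted_protein = as.integer(planted_protein),
               epitope_length = as.integer(epitope_length),
               epitope_mutations = as.integer(epitope_mutations),
               shared_epitope = isTRUE(shared_epitope),
               motif_family_size = as.integer(motif_family_size),
               motif_protein = as.integer(motif_protein))
  if (spec$n_epitope_peptides > spec$n_unique)
    abort("n_epitope_peptides cannot exceed n_unique.")
  if (spec$epitope_length > spec$peptide_length_range[1])
    abort(sprintf("Epitope length %d exceeds the shortest peptide length %d.",
                  spec$epitope_length, spec$peptide_length_range[1]))
  if (spec$n_epitope_peptides > 0 && is.na(spec$planted_protein))
    abort("planted_protein must name a proteome index when carriers are requested.")
  if (spec$motif_family_size > 0 &&
      (spec$motif_family_size < 2 || is.na(spec$motif_protein)))
    abort("A motif family needs motif_family_size >= 2 and a motif_protein index.")
  if (spec$motif_family_size + spec$n_epitope_peptides > spec$n_unique)
    abort("Epitope carriers plus motif family exceed n_unique.")
  structure(spec, class = "panel_spec")
}

#' Configure a synthetic biopanning study
#'
#' @param seed Integer seed; the whole generation is deterministic given the
#'   configuration.
#' @param n_proteins Number of background database proteins (default 300).
#' @param length_meanlog,length_sdlog Lognormal protein-length law (defaults
#'   give a median of 450 aa with a realistic right tail).
#' @param min_protein_length Floor applied to drawn lengths (default 60 aa).
#' @param protein_lengths Optional explicit length vector overriding the
#'   lognormal draw (recycled/truncated to `n_proteins`).
#' @param decoy_lengths Extra very long decoy proteins appended to the
#'   database (default 14507 and 8749 aa — mucin-16- and nesprin-1-sized —
#'   so the length-normalization is always exercised).
#' @param planted_protein_length Length the planted antigen is drawn at when
#'   any panel plants epitopes (default 400 aa).
#' @param aa_frequencies `"uniform"` (default; matches the closed-form chance
#'   rate used in calibration), `"natural"` (vertebrate-proteome
#'   composition), or a named 20-vector of frequencies summing to 1.
#' @param panels List of [panel_spec()] objects.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_proteins = 300L,
                       length_meanlog = log(450), length_sdlog = 0.6,
                       min_protein_length = 60L, protein_lengths = NULL,
                       decoy_lengths = c(14507L, 8749L),
                       planted_protein_length = 400L,
                       aa_frequencies = "uniform",
                       panels = list(panel_spec("A"))) {
  if (is.character(aa_frequencies)) {
    aa_frequencies <- switch(
      match.arg(aa_frequencies, c("uniform", "natural")),
      uniform = setNames(rep(1 / 20, 20), AA_STANDARD),
      natural = AA_NATURAL_FREQS)
  }
  if (length(aa_frequencies) != 20 ||
      abs(sum(aa_frequencies) - 1) > 1e-9 ||
      !setequal(names(aa_frequencies), AA_STANDARD))
    abort("aa_frequencies must be a named 20-vector over the standard amino acids summing to 1.")
  if (inherits(panels, "panel_spec")) panels <- list(panels)
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 min_protein_length = as.integer(min_protein_length),
                 protein_lengths = protein_lengths,
                 decoy_lengths = as.integer(decoy_lengths),
                 planted_protein_length = as.integer(planted_protein_length),
                 aa_frequencies = aa_frequencies[AA_STANDARD],
                 panels = panels),
            class = "sim_config")
}

# draw a uniform integer in [lo, hi] without the scalar-range sample() trap
rint <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

random_seq <- function(len, freqs) {
  paste(sample(AA_STANDARD, len, replace = TRUE, prob = freqs), collapse = "")
}

mutate_seq <- function(seq, n_mut, freqs) {
  if (n_mut == 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(v), min(n_mut, length(v)))
  for (p in pos) {
    v[p] <- sample(setdiff(AA_STANDARD, v[p]), 1,
                   prob = freqs[setdiff(AA_STANDARD, v[p])])
  }
  paste(v, collapse = "")
}

#' Generate a synthetic proteome and biopanning panels with ground truth
#'
#' Draws a protein database (i.i.d. residues from the configured composition,
#' lognormal lengths plus fixed very long decoys) and per-panel peptide sets:
#' epitope carriers embedding planted epitope(s) of a chosen protein at
#' random offsets, an optional shared-motif family whose 4-mer also occurs in
#' a designated database protein, and random background peptides, each with a
#' geometric clonal copy number. Deterministic for a fixed configuration.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `proteome.fasta`,
#'   `panels.tsv` and `truth.json` there.
#' @return A list with `proteome` (tibble), `panels` (tibble) and `truth`
#'   (list: per-panel epitopes, carrier peptides, motif families, planted and
#'   decoy protein ids) — sufficient to score any pipeline run against the
#'   planted ground truth.
#' @export
simulate_screen <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    freqs <- config$aa_frequencies
    lengths <- if (!is.null(config$protein_lengths)) {
      rep_len(as.integer(config$protein_lengths), config$n_proteins)
    } else {
      pmax(config$min_protein_length,
           as.integer(round(stats::rlnorm(config$n_proteins,
                                          config$length_meanlog,
                                          config$length_sdlog))))
    }
    planted_idx <- unique(stats::na.omit(vapply(config$panels,
                                                `[[`, integer(1), "planted_protein")))
    if (any(planted_idx > config$n_proteins))
      abort("planted_protein index exceeds n_proteins.")
    lengths[planted_idx] <- config$planted_protein_length
    ids <- sprintf("SYNP%04d", seq_len(config$n_proteins))
    seqs <- vapply(lengths, random_seq, character(1), freqs = freqs)
    decoy_ids <- character(0)
    if (length(config$decoy_lengths) > 0) {
      decoy_ids <- sprintf("SYNDECOY%d_L%d", seq_along(config$decoy_lengths),
                           config$decoy_lengths)
      ids <- c(ids, decoy_ids)
      lengths <- c(lengths, config$decoy_lengths)
      seqs <- c(seqs, vapply(config$decoy_lengths, random_seq, character(1),
                             freqs = freqs))
    }
    proteome <- tibble::tibble(
      protein_id = ids,
      description = ifelse(ids %in% decoy_ids,
                           "synthetic long decoy protein",
                           "synthetic background protein"),
      sequence = seqs, length_aa = nchar(seqs))
    proteome$description[planted_idx] <- "synthetic planted antigen"

    truth <- list(decoy_protein_ids = decoy_ids, panels = list())
    rows <- list()
    for (spec in config$panels) {
      panel_id <- paste(spec$patient_id, spec$antibody_class, sep = "/")
      lmin <- spec$peptide_length_range[1]; lmax <- spec$peptide_length_range[2]
      seqs_panel <- character(0)
      kind <- character(0)
      panel_truth <- list(panel_id = panel_id, planted_protein_id = NA_character_,
                          epitopes = list(), carriers = character(0),
                          motif = NA_character_, motif_protein_id = NA_character_,
                          motif_family = character(0))

      if (spec$n_epitope_peptides > 0) {
        prot_seq <- proteome$sequence[spec$planted_protein]
        panel_truth$planted_protein_id <- proteome$protein_id[spec$planted_protein]
        L <- nchar(prot_seq); el <- spec$epitope_length
        n_sites <- if (spec$shared_epitope) 1L else spec$n_epitope_peptides
        # non-overlapping epitope sites
        repeat {
          sites <- sort(sample(seq_len(L - el + 1), n_sites))
          if (n_sites == 1 || all(diff(sites) >= el)) break
        }
        epis <- substr(rep(prot_seq, n_sites), sites, sites + el - 1)
        panel_truth$epitopes <- purrr::map2(epis, sites,
                                            ~ list(sequence = .x, site = .y))
        for (ci in seq_len(spec$n_epitope_peptides)) {
          epi <- if (spec$shared_epitope) epis[1] else epis[ci]
          epi <- mutate_seq(epi, spec$epitope_mutations, freqs)
          repeat {
            plen <- rint(lmin, lmax)
            off <- rint(0L, plen - el)
            pep <- paste0(
              random_seq(off, freqs), epi,
              random_seq(plen - el - off, freqs))
            if (!pep %in% seqs_panel) break
          }
          seqs_panel <- c(seqs_panel, pep); kind <- c(kind, "carrier")
        }
        panel_truth$carriers <- seqs_panel[kind == "carrier"]
      }

      if (spec$motif_family_size > 0) {
        mot_seq <- proteome$sequence[spec$motif_protein]
        panel_truth$motif_protein_id <- proteome$protein_id[spec$motif_protein]
        site <- sample(seq_len(nchar(mot_seq) - 3), 1)
        motif <- substr(mot_seq, site, site + 3)
        panel_truth$motif <- motif
        for (mi in seq_len(spec$motif_family_size)) {
          repeat {
            plen <- rint(lmin, lmax)
            off <- rint(0L, plen - 4L)
            pep <- paste0(random_seq(off, freqs), motif,
                          random_seq(plen - 4 - off, freqs))
            if (!pep %in% seqs_panel) break
          }
          seqs_panel <- c(seqs_panel, pep); kind <- c(kind, "motif")
        }
        panel_truth$motif_family <- seqs_panel[kind == "motif"]
      }

      while (length(seqs_panel) < spec$n_unique) {
        pep <- random_seq(rint(lmin, lmax), freqs)
        if (!pep %in% seqs_panel) {
          seqs_panel <- c(seqs_panel, pep); kind <- c(kind, "background")
        }
      }
      copies <- stats::rgeom(length(seqs_panel), spec$copy_geom_prob) + 1L
      rows[[length(rows) + 1]] <- tibble::tibble(
        patient_id = spec$patient_id, antibody_class = spec$antibody_class,
        sequence = seqs_panel, copy_number = copies,
        source_label = paste0("synthetic:", kind))
      truth$panels[[panel_id]] <- panel_truth
    }
    panels <- as_peptide_panels(dplyr::bind_rows(rows))

    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_proteome(proteome, file.path(out_dir, "proteome.fasta"))
      write_panels(panels, file.path(out_dir, "panels.tsv"))
      jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    list(proteome = proteome, panels = panels, truth = truth)
  })
}
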
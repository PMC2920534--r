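test_that("binomial tail reproduces the two-of-three antigen calculation", {
  p0 <- chance_prob(0.02, 403)
  got <- binomial_tail(3, 2, p0)
  # independently: closed form and full 3-trial outcome enumeration
  expect_equal(got, 1 - (1 - p0)^3 - 3 * p0 * (1 - p0)^2, tolerance = 1e-12)
  expect_equal(got, oracle_binom3_tail(2, p0), tolerance = 1e-12)
  expect_lt(got, 0.001)
  # k = 0 is certainty; degenerate edges
  expect_equal(binomial_tail(5, 0, 0.3), 1)
  expect_equal(binomial_tail(3, 3, 1), 1)
  expect_equal(binomial_tail(3, 1, 0), 0)
  expect_error(binomial_tail(3, 4, 0.1), "k must be")
  # cross-check against the distribution function on a grid
  for (n in c(3, 24, 70)) {
    for (k in c(1, 2, min(n, 7))) {
      for (p in c(0.001, 0.0806, 0.29014)) {
        expect_equal(binomial_tail(n, k, p),
                     stats::pbinom(k - 1, n, p, lower.tail = FALSE),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("binomial tail is monotone in k and in p0", {
  for (n in c(3, 10, 70)) {
    p_by_k <- binomial_tail(rep(n, n + 1), 0:n, 0.1)
    expect_true(all(diff(p_by_k) <= 1e-15))
    ps <- seq(0.01, 0.99, by = 0.07)
    p_by_p0 <- vapply(ps, function(p) binomial_tail(n, 2, p), numeric(1))
    expect_true(all(diff(p_by_p0) >= -1e-15))
  }
})

test_that("Fisher contrast equals enumeration on the reconstructable tables", {
  # two of three panel peptides vs none of the 67 others
  expect_equal(fisher_contrast(2, 3, 0, 67), 3 / choose(70, 2),
               tolerance = 1e-12)
  expect_equal(fisher_contrast(2, 3, 0, 67), oracle_fisher_greater(2, 3, 0, 67),
               tolerance = 1e-12)
  # four of 24 vs none of 46
  expect_equal(fisher_contrast(4, 24, 0, 46), choose(24, 4) / choose(70, 4),
               tolerance = 1e-12)
  expect_equal(fisher_contrast(0, 3, 0, 67), 1)
  # agreement with the standard implementation, both sidedness conventions
  set.seed(41)
  for (rep in 1:25) {
    n1 <- sample(1:30, 1); n2 <- sample(1:40, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE)
    expect_equal(fisher_contrast(k1, n1, k2, n2),
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
    expect_equal(fisher_contrast(k1, n1, k2, n2, alternative = "two.sided"),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_contrast(4, 3, 0, 67), "k <= n")
})

test_that("motif collapse separates shared-site from independent matches", {
  # five peptides all matching one protein through a common PWSK site
  pwsk <- tibble::tibble(
    sequence = sprintf("pep%d", 1:5),
    p_start = c(10L, 9L, 10L, 11L, 10L),
    p_end = c(13L, 13L, 14L, 14L, 13L),
    matched_substring = c("PWSK", "APWSK", "PWSKV", "WSKVT", "PWSK"))
  pwsk$matched_substring <- c("PWSK", "APWSK", "PWSKV", "PWSKV", "PWSK")
  cl <- collapse_motif_redundancy(pwsk)
  expect_equal(cl$k_eff, 1L)
  expect_equal(cl$shared_motif, "PWSK")

  # four different peptides at four disjoint sites, no common motif
  free <- tibble::tibble(
    sequence = sprintf("pep%d", 1:4),
    p_start = c(5L, 50L, 120L, 300L), p_end = c(9L, 54L, 124L, 304L),
    matched_substring = c("AKYRW", "QNPGE", "TSKMN", "GVRGQ"))
  cl <- collapse_motif_redundancy(free)
  expect_equal(cl$k_eff, 4L)
  expect_true(is.na(cl$shared_motif))

  # single matching peptide: one group, no motif reported
  one <- collapse_motif_redundancy(pwsk[1, ])
  expect_equal(one$k_eff, 1L)
  expect_true(is.na(one$shared_motif))
  expect_equal(collapse_motif_redundancy(pwsk[0, ])$k_eff, 0L)

  # overlap without a shared >= 4-mer does not collapse
  near <- tibble::tibble(sequence = c("a", "b"),
                         p_start = c(10L, 12L), p_end = c(14L, 16L),
                         matched_substring = c("AKYRW", "YRWGG"))
  expect_equal(collapse_motif_redundancy(near)$k_eff, 2L)
})

test_that("collapse is transitive across chained overlaps", {
  chain <- tibble::tibble(
    sequence = c("a", "b", "c"),
    p_start = c(10L, 12L, 14L), p_end = c(15L, 17L, 19L),
    matched_substring = c("QWERTY", "ERTYUI", "TYUIOP") |>
      (\(x) gsub("O|U", "G", x))())
  expect_equal(collapse_motif_redundancy(chain)$k_eff, 1L)
})

test_that("ranking integrates collapse, both tests, flags and ordering", {
  set.seed(61)
  # panel X: two peptides carry distinct epitopes of ANT (400 aa);
  # panel Y: background only; decoy BIG (5000 aa) catches one X peptide
  ant <- random_aa(400)
  epi1 <- substr(ant, 30, 36); epi2 <- substr(ant, 200, 206)
  pepX <- c(paste0(random_aa(2), epi1, random_aa(1)),
            paste0(random_aa(1), epi2, random_aa(2)),
            random_aa(9))
  big <- paste0(random_aa(2000), pepX[3], random_aa(5000 - 2000 - 9))
  panels <- dplyr::bind_rows(
    make_panel(pepX, patient_id = "X"),
    make_panel(vapply(1:10, function(i) random_aa(9), ""), patient_id = "Y"))
  prot <- make_proteome(c(ant, big, random_aa(350)), c("ANT", "BIG", "BKG"))
  params <- match_params()
  hits <- search_panels(panels, prot, params)
  null <- null_estimate(0.02, 0.01, 13, params = params)
  cand <- rank_candidates(hits, panels, prot, null)

  x <- dplyr::filter(cand, panel_id == "X/IgG")
  expect_equal(x$protein_id[1], "ANT")
  expect_equal(x$k_eff[x$protein_id == "ANT"], 2L)
  expect_equal(x$n[x$protein_id == "ANT"], 3L)
  p0 <- chance_prob(0.02, 400)
  expect_equal(x$p_binomial[x$protein_id == "ANT"],
               binomial_tail(3, 2, p0), tolerance = 1e-12)
  expect_equal(x$p_fisher[x$protein_id == "ANT"],
               fisher_contrast(2, 3, 0, 10), tolerance = 1e-12)
  expect_equal(x$other_total[1], 10L)
  # the full-length decoy catch: k = 1 with expected chance matches
  # n*p0 = 3*0.1 < 1, so no LENGTH_SUSPECT at this length
  expect_equal(x$flags[x$protein_id == "BIG"], "")
  expect_equal(x$rank, seq_len(nrow(x)))

  # a very long protein accumulating only chance-level matches is flagged
  null70 <- null_estimate(0.02, 0.01, 70, params = params)
  mucin_hits <- tibble::tibble(
    panel_id = "Z/IgG", sequence = sprintf("PEP%dAAA", 1:7) |>
      (\(x) vapply(1:7, function(i) random_aa(8), ""))(),
    protein_id = "MUC", p_start = seq(1, 1301, length.out = 7) |> round() |> as.integer(),
    p_end = NA_integer_, pep_start = 1L,
    matched_substring = vapply(1:7, function(i) random_aa(5), ""), score = 5L)
  mucin_hits$p_end <- mucin_hits$p_start + 4L
  attr(mucin_hits, "match_params") <- params
  panelsZ <- make_panel(vapply(1:70, function(i) random_aa(8), ""),
                        patient_id = "Z")
  panelsZ$sequence[1:7] <- mucin_hits$sequence
  protZ <- tibble::tibble(protein_id = "MUC", description = "",
                          sequence = NA_character_, length_aa = 14507L)
  candZ <- rank_candidates(mucin_hits, panelsZ, protZ, null70)
  expect_equal(candZ$k, 7L)
  expect_gt(candZ$p_binomial, 0.999)
  expect_match(candZ$flags, "LENGTH_SUSPECT")
})

test_that("collapse never increases significance", {
  set.seed(91)
  for (rep in 1:20) {
    n <- sample(5:30, 1); k <- sample(2:5, 1); k_eff <- sample(1:k, 1)
    p0 <- runif(1, 0, 0.3)
    expect_gte(binomial_tail(n, k_eff, p0), binomial_tail(n, k, p0))
  }
})

test_that("mismatched forward/null parameters are a hard error", {
  pan <- make_panel(c("FQSPKAY", "KYRWYKA"))
  prot <- make_proteome("MMFQSPKAYDD", "P1")
  p1 <- match_params(min_exact_window = 5)
  p2 <- match_params(min_exact_window = 4)
  hits <- search_panels(pan, prot, p1)
  null_other <- null_estimate(0.02, 0.01, 70, params = p2)
  expect_error(rank_candidates(hits, pan, prot, null_other), "identical match")
  # external hits (no params) against an internal null: also refused
  h2 <- hits; attr(h2, "match_params") <- NULL
  expect_error(rank_candidates(h2, pan, prot,
                               null_estimate(0.02, 0.01, 70, params = p1)),
               "identical match")
  # both external: accepted
  expect_s3_class(rank_candidates(h2, pan, prot,
                                  null_estimate(0.02, 0.01, 70)),
                  "candidate_results")
})

test_that("panels with no matches yield no candidate rows", {
  pan <- make_panel(c("WWWWWWW", "YYYYYYY"))
  prot <- make_proteome("AAAAAAAAAAAAAAA", "P1")
  params <- match_params()
  hits <- search_panels(pan, prot, params)
  cand <- rank_candidates(hits, pan, prot,
                          null_estimate(0.02, 0.01, 70, params = params))
  expect_equal(nrow(cand), 0)
})

test_that("under a fully null run the binomial p-values are conservative", {
  # no planted antigen: over panels x proteins, the fraction with
  # p_binomial < alpha must stay below 2*alpha (the thresholded null is
  # inflated by construction)
  alpha <- 0.05
  n_sig <- 0L; n_tot <- 0L
  for (seed in 1:10) {
    sim <- simulate_screen(sim_config(
      seed = seed, n_proteins = 80, decoy_lengths = integer(0),
      panels = list(panel_spec("A", n_unique = 10),
                    panel_spec("B", n_unique = 10))))
    params <- match_params()
    hits <- search_panels(sim$panels, sim$proteome, params)
    null <- tryCatch(
      suppressWarnings(estimate_null(sim$panels, sim$proteome, params,
                                     min_matches_threshold = 0)),
      error = function(e) NULL)
    if (is.null(null) || nrow(hits) == 0) next
    cand <- rank_candidates(hits, sim$panels, sim$proteome, null)
    n_sig <- n_sig + sum(cand$p_binomial < alpha)
    n_tot <- n_tot + 2L * nrow(sim$proteome)
  }
  expect_gt(n_tot, 0)
  expect_lte(n_sig / n_tot, 2 * alpha)
})

test_that("enrichment QC applies the twofold rule at the boundary", {
  qc <- enrichment_qc(c(200, 150, 0), c(100, 100, 100))
  expect_equal(qc$ratio, c(2, 1.5, 0))
  expect_equal(qc$pass, c(TRUE, FALSE, FALSE))
  expect_error(enrichment_qc(100, 0), "cfu_control")
})

test_that("expression cross-check flags only patient-unique overexpression", {
  cand <- tibble::tibble(panel_id = c("A/IgG", "A/IgG", "A/IgG"),
                         protein_id = c("P1", "P2", "P3"),
                         flags = c("", "MOTIF_COLLAPSED", ""))
  expr <- tibble::tibble(gene_id = c("G1", "G2"),
                         s1 = c(10, 10), s2 = c(4, 6), s3 = c(1, 2))
  gmap <- tibble::tibble(protein_id = c("P1", "P2"), gene_id = c("G1", "G2"))
  pmap <- tibble::tibble(patient_id = "A", sample_id = "s1")
  expect_warning(expression_cross_check(cand, expr, gmap, pmap), "P3")
  out <- suppressWarnings(expression_cross_check(cand, expr, gmap, pmap))
  expect_equal(out$flags,
               c("EXPRESSION_SUPPORTED", "MOTIF_COLLAPSED", ""))
  # 10 vs max 6 elsewhere: below twofold, not flagged
  # 14-sample profile: high only in the patient's own tumor
  expr14 <- tibble::as_tibble(c(list(gene_id = "G1"),
                                stats::setNames(as.list(runif(13, 0.5, 1.5)),
                                                sprintf("s%d", 2:14)),
                                list(s1 = 20)))
  out14 <- expression_cross_check(cand[1, ], expr14, gmap[1, ], pmap)
  expect_match(out14$flags, "EXPRESSION_SUPPORTED")
})
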
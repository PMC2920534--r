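# Independent oracles used across the suite. Each re-derives the quantity a
# package function computes, by a deliberately different route (direct
# per-window checks, exhaustive enumeration, closed forms), so that
# implementation and oracle share no code path.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_aa <- function(n, freqs = NULL) {
  paste(sample(AA20, n, replace = TRUE, prob = freqs), collapse = "")
}

# Brute-force exact-mode matcher: enumerate every (diagonal, start, length)
# window, keep windows with length >= wmin and at most maxmm mismatches that
# cannot be extended one residue in either direction without leaving the
# sequences or exceeding the budget. Returns 1-based inclusive coordinates.
oracle_exact_hits <- function(pep, prot, wmin, maxmm) {
  pv <- strsplit(pep, "")[[1]]; qv <- strsplit(prot, "")[[1]]
  lp <- length(pv); lq <- length(qv)
  out <- list()
  for (o in (-(lp - 1)):(lq - 1)) {          # o = prot_pos - pep_pos (0-based)
    i_lo <- max(1, 1 - o); i_hi <- min(lp, lq - o)
    if (i_hi - i_lo + 1 < wmin) next
    mism <- as.integer(pv[i_lo:i_hi] != qv[(i_lo + o):(i_hi + o)])
    cs <- c(0L, cumsum(mism))
    nwin <- i_hi - i_lo + 1
    for (a in seq_len(nwin)) {
      if (nwin - a + 1 < wmin) break
      for (len in wmin:(nwin - a + 1)) {
        mm_in <- cs[a + len] - cs[a]
        if (mm_in > maxmm) next
        left_ok <- (a == 1) || (mm_in + mism[a - 1] > maxmm)
        right_ok <- (a + len - 1 == nwin) || (mm_in + mism[a + len] > maxmm)
        if (left_ok && right_ok) {
          pep_start <- i_lo + a - 1
          out[[length(out) + 1]] <- c(pep_start = pep_start,
                                      p_start = pep_start + o, len = len)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(pep_start = integer(0), p_start = integer(0),
                      len = integer(0)))
  }
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$p_start, df$pep_start, df$len), , drop = FALSE]
}

# Closed-form probability that a random lp-mer shares at least one exact
# w-window with a random L-mer (i.i.d. uniform residues), treating window
# pairs as independent.
closed_form_hit_prob <- function(lp, L, w) {
  1 - (1 - 20^(-w))^((lp - w + 1) * (L - w + 1))
}

# Exhaustive hypergeometric enumeration for the one-sided Fisher contrast,
# via explicit binomial-coefficient ratios (no dhyper).
oracle_fisher_greater <- function(k1, n1, k2, n2) {
  c1 <- k1 + k2
  xs <- max(0, c1 - n2):min(n1, c1)
  probs <- choose(n1, xs) * choose(n2, c1 - xs) / choose(n1 + n2, c1)
  min(1, sum(probs[xs >= k1]))
}

# Three-trial outcome-space enumeration of P(X >= k) for X ~ Binomial(3, p):
# sums the probability of every explicit success/failure triple.
oracle_binom3_tail <- function(k, p) {
  grid <- expand.grid(c(0, 1), c(0, 1), c(0, 1))
  succ <- rowSums(grid)
  probs <- apply(grid, 1, function(g) prod(ifelse(g == 1, p, 1 - p)))
  sum(probs[succ >= k])
}

# Brute-force shared-motif enumeration: every wildcard pattern (wildcards
# never terminal) occurring in >= 2 distinct sequences, maximality by
# member-set containment, checked by sliding-window matching without regex.
oracle_motifs <- function(seqs, min_len, max_len, max_wildcards) {
  match_at <- function(pat, sv) {
    lp <- length(pat)
    if (lp > length(sv)) return(FALSE)
    for (off in 0:(length(sv) - lp)) {
      if (all(pat == "x" | pat == sv[(off + 1):(off + lp)])) return(TRUE)
    }
    FALSE
  }
  seqv <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  pats <- list()
  for (sv in seqv) {
    n <- length(sv)
    for (len in min_len:min(max_len, n)) {
      for (st in 1:(n - len + 1)) {
        base <- sv[st:(st + len - 1)]
        variants <- list(base)
        if (max_wildcards > 0 && len > 2) {
          for (w in 1:min(max_wildcards, len - 2)) {
            for (pos in utils::combn(2:(len - 1), w, simplify = FALSE)) {
              v <- base; v[pos] <- "x"; variants[[length(variants) + 1]] <- v
            }
          }
        }
        for (v in variants) pats[[paste(v, collapse = "")]] <- v
      }
    }
  }
  members <- lapply(pats, function(p) seqs[vapply(seqv, match_at, logical(1), pat = p)])
  keep <- lengths(members) >= 2
  pats <- pats[keep]; members <- members[keep]
  if (length(pats) == 0) return(character(0))
  keys <- vapply(members, function(m) paste(sort(m), collapse = "\r"), character(1))
  contained <- function(a, b) {
    if (length(a) > length(b)) return(FALSE)
    for (off in 0:(length(b) - length(a))) {
      if (all(a == "x" | a == b[(off + 1):(off + length(a))])) return(TRUE)
    }
    FALSE
  }
  keep <- rep(TRUE, length(pats))
  for (i in seq_along(pats)) {
    for (j in seq_along(pats)) {
      if (i != j && keys[i] == keys[j] && contained(pats[[i]], pats[[j]])) {
        keep[i] <- FALSE; break
      }
    }
  }
  sort(names(pats)[keep])
}

make_panel <- function(sequences, copy_number = 1L, patient_id = "T",
                       antibody_class = "IgG") {
  as_peptide_panels(tibble::tibble(
    patient_id = patient_id, antibody_class = antibody_class,
    sequence = sequences,
    copy_number = rep_len(copy_number, length(sequences))))
}

make_proteome <- function(sequences, ids = NULL) {
  tibble::tibble(
    protein_id = ids %||% sprintf("P%d", seq_along(sequences)),
    description = "", sequence = toupper(sequences),
    length_aa = nchar(sequences))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
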
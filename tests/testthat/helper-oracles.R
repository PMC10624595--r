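# Independent oracles and tiny generators used across the suite. Each
# oracle is deliberately naive (enumeration / brute force) and shares no
# code with the implementation paths it checks.

# exhaustive global-alignment oracle: enumerate every alignment as a move
# sequence and score the final strings directly (gap run of length L costs
# open + (L-1)*extend)
oracle_best_alignment_score <- function(a, b, sc) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  score_aln <- function(sa, sb) {
    s <- 0; run_a <- 0; run_b <- 0
    for (k in seq_along(sa)) {
      if (sa[k] == "-") {
        run_a <- run_a + 1; run_b <- 0
        s <- s - (if (run_a == 1) sc$gap_open else sc$gap_extend)
      } else if (sb[k] == "-") {
        run_b <- run_b + 1; run_a <- 0
        s <- s - (if (run_b == 1) sc$gap_open else sc$gap_extend)
      } else {
        run_a <- 0; run_b <- 0
        s <- s + sc$S[sa[k], sb[k]]
      }
    }
    s
  }
  best <- -Inf
  rec <- function(i, j, sa, sb) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score_aln(sa, sb))
      return(invisible())
    }
    if (i <= length(av)) rec(i + 1, j, c(sa, av[i]), c(sb, "-"))
    if (j <= length(bv)) rec(i, j + 1, c(sa, "-"), c(sb, bv[j]))
    if (i <= length(av) && j <= length(bv)) rec(i + 1, j + 1, c(sa, av[i]), c(sb, bv[j]))
  }
  rec(1L, 1L, character(0), character(0))
  best
}

# independent a3m -> aligned expansion: per-row (match, insertion) slots,
# then per-slot column blocks, right-padded with gaps
oracle_a3m_expand <- function(rows) {
  decomp <- lapply(rows, function(r) {
    chars <- strsplit(r, "")[[1]]
    m <- character(0); ins <- list(character(0))
    for (ch in chars) {
      if (grepl("[a-z]", ch)) {
        ins[[length(ins)]] <- c(ins[[length(ins)]], ch)
      } else {
        m <- c(m, ch); ins[[length(ins) + 1L]] <- character(0)
      }
    }
    list(m = m, ins = ins)
  })
  n_slots <- length(decomp[[1L]]$ins)
  widths <- vapply(seq_len(n_slots), function(s) {
    max(vapply(decomp, function(d) length(d$ins[[s]]), integer(1)))
  }, integer(1))
  vapply(decomp, function(d) {
    out <- character(0)
    for (s in seq_len(n_slots)) {
      blk <- toupper(d$ins[[s]])
      out <- c(out, blk, rep("-", widths[s] - length(blk)))
      if (s < n_slots) out <- c(out, d$m[s])
    }
    paste(out, collapse = "")
  }, character(1))
}

# random a3m with a gapless query row
gen_random_a3m <- function(n_rows = 4L, L = 8L, seed = 1L) {
  set.seed(seed)
  ab <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  query <- paste(sample(ab, L, TRUE), collapse = "")
  rows <- query
  for (i in seq_len(n_rows - 1L)) {
    chars <- character(0)
    for (p in seq_len(L)) {
      chars <- c(chars, if (stats::runif(1) < 0.2) "-" else sample(ab, 1L))
      if (stats::runif(1) < 0.15) {
        chars <- c(chars, tolower(sample(ab, sample(1:2, 1L), TRUE)))
      }
    }
    rows <- c(rows, paste(chars, collapse = ""))
  }
  msa(paste0("r", seq_len(n_rows)), rows, dialect = "A3M")
}

# brute-force residue-level identity (independent of pairwise_identity)
oracle_identity_coverage <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  num <- sum(ca == cb & ca != "-")
  den <- sum(ca != "-" | cb != "-")
  if (den == 0) 0 else num / den
}

# exhaustive minimum-weight SG matching (all perfect-or-partial matchings
# under the cutoff) for small point sets; returns the pair set minimising
# total distance among matchings of maximum cardinality
oracle_sg_matching <- function(xyz, cutoff) {
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  cand <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(matrix(integer(0), ncol = 2L))
  best <- NULL; best_card <- -1L; best_w <- Inf
  rec <- function(k, used, chosen, w) {
    if (k > nrow(cand)) {
      card <- length(chosen) / 2L
      if (card > best_card || (card == best_card && w < best_w)) {
        best <<- matrix(chosen, ncol = 2L, byrow = TRUE)
        best_card <<- card; best_w <<- w
      }
      return(invisible())
    }
    i <- cand[k, 1L]; j <- cand[k, 2L]
    if (!used[i] && !used[j]) {
      used2 <- used; used2[c(i, j)] <- TRUE
      rec(k + 1L, used2, c(chosen, i, j), w + d[i, j])
    }
    rec(k + 1L, used, chosen, w)
  }
  rec(1L, logical(n), integer(0), 0)
  best
}

random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# apply a rigid transform to every atom of a structure_model
transform_model <- function(model, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  model$atoms$x <- xyz[, 1L] + t[1L]
  model$atoms$y <- xyz[, 2L] + t[2L]
  model$atoms$z <- xyz[, 3L] + t[3L]
  model
}
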
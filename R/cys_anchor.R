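## Cysteine-anchored alignment machinery.
##
## Small defensin-like proteins carry 8-10 cysteines whose disulfide
## scaffold is conserved even when the inter-cysteine segments are not.
## Generic aligners routinely misplace those cysteines; the tools here pin
## structurally homologous cysteines ("anchors") to shared columns:
##   barcode/debarcode - replace anchor cysteines with rare placeholder
##     letters before running an external aligner, then restore them;
##   anchor_align      - a self-contained anchor-constrained aligner that
##     splits sequences at their anchors and aligns each inter-anchor
##     segment independently by center-star alignment;
##   merge_into_msa    - add a sequence to an existing alignment through a
##     pairwise alignment with its closest row.

DEFAULT_PLACEHOLDERS <- "BJOUZ0123456789"

cys_placeholders_chars <- function() strsplit(DEFAULT_PLACEHOLDERS, "")[[1]]

#' Default placeholder alphabet for cysteine barcoding
#'
#' Letters that do not occur in the package's amino-acid alphabet (`X` is a
#' residue here, so it is excluded), extended with digits for 10-cysteine
#' proteins. External aligners with strict alphabets may reject the digit
#' placeholders; a warning is emitted when more than six slots are barcoded.
#'
#' @return A single string of placeholder characters, in slot order.
#' @export
cys_placeholders <- function() DEFAULT_PLACEHOLDERS

#' Disulfide connectivity pattern
#'
#' A named set of disulfide pairs in 1-based ordinals of cysteine occurrence
#' along the sequence (e.g. `1-8, 2-5, 3-6, 4-7` for the common 8-cysteine
#' defensin scaffold).
#'
#' @param name Pattern name.
#' @param n_cys Number of cysteines the pattern applies to.
#' @param pairs Two-column integer matrix of ordinal pairs.
#' @return An object of class `connectivity_pattern`.
#' @export
connectivity_pattern <- function(name, n_cys, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  pairs <- t(apply(pairs, 1L, sort))
  ord <- as.vector(pairs)
  if (any(ord < 1L) || any(ord > n_cys)) stop("ordinals must lie in 1..n_cys")
  if (anyDuplicated(ord)) stop("every ordinal may appear in at most one pair")
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  structure(list(name = name, n_cys = as.integer(n_cys), pairs = pairs),
            class = "connectivity_pattern")
}

#' Built-in connectivity catalog
#'
#' The five patterns observed across SP11/defensin-like structure groups:
#' the prevalent 8-cysteine pattern `DEF8` (1-8, 2-5, 3-6, 4-7), three
#' 10-cysteine groups `TEN_A` (1-10, 2-6, 3-7, 4-9, 5-8), `TEN_B`
#' (1-9, 2-10, 3-6, 4-7, 5-8), `TEN_C` (1-10, 2-5, 3-7, 4-8, 6-9), and the
#' anomalous 8-cysteine `EIGHT_ALT` (1-4, 2-6, 3-7, 5-8).
#'
#' @return Named list of [connectivity_pattern()] objects.
#' @export
connectivity_catalog <- function() {
  list(
    DEF8      = connectivity_pattern("DEF8", 8L,
                  rbind(c(1, 8), c(2, 5), c(3, 6), c(4, 7))),
    TEN_A     = connectivity_pattern("TEN_A", 10L,
                  rbind(c(1, 10), c(2, 6), c(3, 7), c(4, 9), c(5, 8))),
    TEN_B     = connectivity_pattern("TEN_B", 10L,
                  rbind(c(1, 9), c(2, 10), c(3, 6), c(4, 7), c(5, 8))),
    TEN_C     = connectivity_pattern("TEN_C", 10L,
                  rbind(c(1, 10), c(2, 5), c(3, 7), c(4, 8), c(6, 9))),
    EIGHT_ALT = connectivity_pattern("EIGHT_ALT", 8L,
                  rbind(c(1, 4), c(2, 6), c(3, 7), c(5, 8)))
  )
}

#' Read a connectivity catalog from a plain-text table
#'
#' Tab-separated columns: name, n_cys, pair list (`1-8,2-5,...`). Lines
#' starting with `#` are comments.
#'
#' @param path File path.
#' @return Named list of [connectivity_pattern()] objects.
#' @export
read_connectivity_table <- function(path) {
  lines <- read_lines_any(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  pats <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) != 3L) stop("malformed connectivity table line: ", sQuote(l))
    pr <- do.call(rbind, lapply(strsplit(f[3L], ",", fixed = TRUE)[[1]], function(p) {
      as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
    }))
    connectivity_pattern(f[1L], as.integer(f[2L]), pr)
  })
  stats::setNames(pats, vapply(pats, `[[`, character(1), "name"))
}

#' Per-sequence anchor slot assignment
#'
#' Maps each global anchor slot (1..K) to the index of the sequence's
#' cysteine occurrence filling it, or `NA` when the slot is absent (e.g. a
#' 7-cysteine member of an 8-cysteine family).
#'
#' @param sequence_id Sequence id.
#' @param slot_map Integer vector of length K; `NA` marks an absent slot.
#' @return An object of class `anchor_assignment`.
#' @export
anchor_assignment <- function(sequence_id, slot_map) {
  slot_map <- as.integer(slot_map)
  filled <- slot_map[!is.na(slot_map)]
  if (anyDuplicated(filled)) stop("a slot maps two anchor slots to one cysteine")
  structure(list(sequence_id = sequence_id, slot_map = slot_map),
            class = "anchor_assignment")
}

#' Positions of cysteine residues
#'
#' @param seq A [seq_record()] or a residue string.
#' @return Strictly increasing 1-based positions of `C`.
#' @export
find_cysteines <- function(seq) {
  res <- if (inherits(seq, "seq_record")) seq$residues else seq
  which(strsplit(res, "")[[1]] == "C")
}

#' Replace anchor cysteines with placeholder letters
#'
#' The cysteine filling slot k becomes `placeholders[k]`; unassigned
#' cysteines and all other residues are untouched. The barcoded sequence
#' can be fed to an external aligner so that homologous cysteines align,
#' then restored with [debarcode()].
#'
#' @param seq A [seq_record()].
#' @param assign An [anchor_assignment()] for this sequence.
#' @param placeholders Ordered placeholder string (default
#'   [cys_placeholders()]).
#' @return A barcoded [seq_record()].
#' @export
barcode <- function(seq, assign, placeholders = cys_placeholders()) {
  stopifnot(inherits(seq, "seq_record"), inherits(assign, "anchor_assignment"))
  K <- length(assign$slot_map)
  if (K > nchar(placeholders)) {
    stop(sprintf("slot count (%d) exceeds placeholder alphabet (%d)",
                 K, nchar(placeholders)))
  }
  if (sum(!is.na(assign$slot_map)) > 6L) {
    warning("more than 6 placeholders in use; strict-alphabet external aligners may object")
  }
  cpos <- find_cysteines(seq)
  chars <- strsplit(seq$residues, "")[[1]]
  ph <- strsplit(placeholders, "")[[1]]
  for (k in seq_len(K)) {
    ci <- assign$slot_map[k]
    if (is.na(ci)) next
    if (ci < 1L || ci > length(cpos)) {
      stop(sprintf("slot %d of '%s' references cysteine occurrence %d, but only %d exist",
                   k, seq$id, ci, length(cpos)))
    }
    if (chars[cpos[ci]] != "C") stop("slot references a non-cysteine position")
    chars[cpos[ci]] <- ph[k]
  }
  seq_record(seq$id, paste(chars, collapse = ""), seq$description,
             alphabet = "barcoded")
}

debarcode_string <- function(x, placeholders) {
  ph <- strsplit(placeholders, "")[[1]]
  letters_ph <- ph[grepl("[A-Z]", ph)]
  if (length(letters_ph) > 0L) {
    lo <- tolower(paste(letters_ph, collapse = ""))
    x <- chartr(lo, strrep("c", nchar(lo)), x)
  }
  up <- paste(ph, collapse = "")
  chartr(up, strrep("C", nchar(up)), x)
}

#' Restore placeholder letters to cysteines
#'
#' Inverse of [barcode()], applied to a whole alignment (or a single
#' sequence): uppercase placeholders (and digit placeholders, which carry no
#' case) become `C`, lowercase placeholders become the insertion-state `c`.
#'
#' @param x An [msa()] or [seq_record()].
#' @param placeholders Placeholder string used at barcode time.
#' @return Object of the same class with placeholders restored.
#' @export
debarcode <- function(x, placeholders = cys_placeholders()) {
  if (inherits(x, "seq_record")) {
    return(seq_record(x$id, debarcode_string(x$residues, placeholders), x$description))
  }
  stopifnot(inherits(x, "msa"))
  msa(x$ids, vapply(x$rows, debarcode_string, character(1),
                    placeholders = placeholders, USE.NAMES = FALSE),
      dialect = x$dialect)
}

## ---- pairwise global alignment (Gotoh, affine gaps) ----

blosum_cache <- new.env(parent = emptyenv())

substitution_matrix <- function(name = "BLOSUM62") {
  if (!exists(name, envir = blosum_cache)) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    assign(name, get(name, envir = e), envir = blosum_cache)
  }
  get(name, envir = blosum_cache)
}

#' Affine-gap scoring scheme
#'
#' A gap run of length L costs `gap_open + (L - 1) * gap_extend`. Defaults:
#' BLOSUM62, open 10, extend 1.
#'
#' @param matrix Substitution matrix name (resolved via Biostrings data).
#' @param gap_open Non-negative gap opening penalty.
#' @param gap_extend Non-negative gap extension penalty, `<= gap_open`.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 1) {
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be non-negative")
  if (gap_extend > gap_open) stop("gap-extend must not exceed gap-open")
  structure(list(matrix_name = matrix, S = substitution_matrix(matrix),
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

# Gotoh global alignment; empty inputs allowed here (exported wrapper
# enforces the non-empty precondition). Tie-breaking is fixed: at equal
# score prefer the diagonal state, then vertical (gap in b), then
# horizontal (gap in a), both for the final state and for every
# predecessor choice, so alignments are byte-identical across runs.
align_global <- function(a, b, scoring) {
  go <- scoring$gap_open; ge <- scoring$gap_extend
  n <- nchar(a); m <- nchar(b)
  gap_cost <- function(L) if (L == 0L) 0 else go + (L - 1L) * ge
  if (n == 0L && m == 0L) return(list(aligned_a = "", aligned_b = "", score = 0))
  if (n == 0L) return(list(aligned_a = strrep("-", m), aligned_b = b, score = -gap_cost(m)))
  if (m == 0L) return(list(aligned_a = a, aligned_b = strrep("-", n), score = -gap_cost(n)))
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  S <- scoring$S
  sub <- S[av, bv, drop = FALSE]          # n x m substitution scores
  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L); X <- M; Y <- M
  PM <- matrix(0L, n + 1L, m + 1L); PX <- PM; PY <- PM   # 1=M, 2=X, 3=Y
  M[1L, 1L] <- 0
  for (i in seq_len(n)) { X[i + 1L, 1L] <- -gap_cost(i); PX[i + 1L, 1L] <- 2L }
  X[2L, 1L] <- -go; PX[2L, 1L] <- 1L
  for (j in seq_len(m)) { Y[1L, j + 1L] <- -gap_cost(j); PY[1L, j + 1L] <- 3L }
  Y[1L, 2L] <- -go; PY[1L, 2L] <- 1L
  pick <- function(vals) which.max(vals + c(2e-9, 1e-9, 0))  # M > X > Y at ties
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      dm <- c(M[i, j], X[i, j], Y[i, j])
      km <- pick(dm)
      M[i + 1L, j + 1L] <- dm[km] + sub[i, j]; PM[i + 1L, j + 1L] <- km
      dx <- c(M[i, j + 1L] - go, X[i, j + 1L] - ge, Y[i, j + 1L] - go)
      kx <- pick(dx)
      X[i + 1L, j + 1L] <- dx[kx]; PX[i + 1L, j + 1L] <- kx
      dy <- c(M[i + 1L, j] - go, X[i + 1L, j] - go, Y[i + 1L, j] - ge)
      ky <- pick(dy)
      Y[i + 1L, j + 1L] <- dy[ky]; PY[i + 1L, j + 1L] <- ky
    }
  }
  fin <- c(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  state <- pick(fin)
  score <- fin[state]
  out_a <- character(0); out_b <- character(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (state == 1L) {
      out_a <- c(av[i], out_a); out_b <- c(bv[j], out_b)
      state <- PM[i + 1L, j + 1L]; i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      out_a <- c(av[i], out_a); out_b <- c("-", out_b)
      state <- PX[i + 1L, j + 1L]; i <- i - 1L
    } else {
      out_a <- c("-", out_a); out_b <- c(bv[j], out_b)
      state <- PY[i + 1L, j + 1L]; j <- j - 1L
    }
  }
  list(aligned_a = paste(out_a, collapse = ""),
       aligned_b = paste(out_b, collapse = ""),
       score = as.numeric(score))
}

#' Optimal pairwise global alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh alignment under a [scoring_scheme()]. The score is
#' the sum of substitution-matrix entries over aligned residue pairs minus
#' `gap_open + (L - 1) * gap_extend` per gap run of length L (terminal gaps
#' included). Deterministic: ties prefer diagonal, then vertical, then
#' horizontal moves.
#'
#' @param a,b [seq_record()] objects or residue strings (non-empty).
#' @param scoring A [scoring_scheme()].
#' @return `list(aligned_a, aligned_b, score)`.
#' @export
pairwise_global_align <- function(a, b, scoring = scoring_scheme()) {
  sa <- if (inherits(a, "seq_record")) a$residues else a
  sb <- if (inherits(b, "seq_record")) b$residues else b
  if (!nzchar(sa) || !nzchar(sb)) stop("sequences must be non-empty")
  align_global(sa, sb, scoring)
}

# fraction of identical aligned residue pairs over alignment length
aligned_fraction_identity <- function(aligned_a, aligned_b) {
  ca <- strsplit(aligned_a, "")[[1]]; cb <- strsplit(aligned_b, "")[[1]]
  sum(ca == cb & ca != "-") / length(ca)
}

## ---- anchor-constrained center-star alignment ----

# split residues into K+1 inter-anchor segments following the slot map;
# residues around an absent anchor flow into the segment preceding it
split_at_anchors <- function(residues, slot_map) {
  cpos <- find_cysteines(residues)
  K <- length(slot_map)
  pos <- ifelse(is.na(slot_map), NA_integer_, cpos[slot_map])
  filled <- pos[!is.na(pos)]
  if (is.unsorted(filled, strictly = TRUE)) {
    stop("anchor slots must map to cysteines in increasing sequence order")
  }
  segs <- rep("", K + 1L)
  cursor <- 1L; last_present <- 0L
  for (k in seq_len(K)) {
    if (is.na(pos[k])) next
    segs[last_present + 1L] <- paste0(segs[last_present + 1L],
                                      substr(residues, cursor, pos[k] - 1L))
    cursor <- pos[k] + 1L
    last_present <- k
  }
  segs[last_present + 1L] <- paste0(segs[last_present + 1L],
                                    substr(residues, cursor, nchar(residues)))
  segs
}

# center-star alignment of a set of strings (possibly empty); returns the
# aligned strings in input order. Pairwise alignments are memoised in `cache`.
center_star <- function(strs, scoring, cache = new.env(parent = emptyenv())) {
  n <- length(strs)
  if (all(!nzchar(strs))) return(rep("", n))
  if (n == 1L) return(strs)
  memo_align <- function(x, y) {
    key <- paste0(x, "\r", y)
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- align_global(x, y, scoring)
    cache[[key]] <- res
    res
  }
  # summed pairwise score per candidate center; ties -> lowest input index
  tot <- numeric(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- memo_align(strs[i], strs[j])$score
      tot[i] <- tot[i] + s; tot[j] <- tot[j] + s
    }
  }
  center <- which.max(tot)
  master <- strsplit(strs[center], "")[[1]]
  aligned <- vector("list", n)
  aligned[[center]] <- master
  for (i in setdiff(seq_len(n), center)) {
    pa <- memo_align(strs[center], strs[i])
    ac <- strsplit(pa$aligned_a, "")[[1]]
    ar <- strsplit(pa$aligned_b, "")[[1]]
    new_master <- character(0); new_row <- character(0)
    patch <- integer(0)   # for each output column, source master column or 0 (new)
    p <- 1L; q <- 1L
    nm <- length(master); nq <- length(ac)
    while (p <= nm || q <= nq) {
      m_gap <- p <= nm && master[p] == "-"
      c_gap <- q <= nq && ac[q] == "-"
      if (m_gap && !c_gap) {
        new_master <- c(new_master, "-"); new_row <- c(new_row, "-")
        patch <- c(patch, p); p <- p + 1L
      } else if (c_gap && !m_gap) {
        new_master <- c(new_master, "-"); new_row <- c(new_row, ar[q])
        patch <- c(patch, 0L); q <- q + 1L
      } else {
        new_master <- c(new_master, master[p]); new_row <- c(new_row, ar[q])
        patch <- c(patch, p); p <- p + 1L; q <- q + 1L
      }
    }
    # re-project previously aligned rows onto the merged column set
    for (k in seq_len(n)) {
      if (k == i || is.null(aligned[[k]])) next
      old <- aligned[[k]]
      aligned[[k]] <- ifelse(patch == 0L, "-", old[pmax(patch, 1L)])
    }
    aligned[[i]] <- new_row
    master <- new_master
  }
  vapply(aligned, paste, character(1), collapse = "")
}

#' Anchor-constrained multiple alignment of cysteine-rich sequences
#'
#' Sequences are split at their assigned anchor cysteines; each of the K
#' anchor slots contributes a single column containing `C` (slot filled) or
#' `-` (slot absent), and each of the K+1 inter-anchor segment slots is
#' aligned independently by center-star alignment (center = segment with the
#' highest summed pairwise score against the others; ties -> lowest input
#' index). A sequence missing an anchor contributes its residues to the
#' segment preceding the absent anchor.
#'
#' @param seqs List of [seq_record()] objects.
#' @param assigns List of [anchor_assignment()] objects, parallel to `seqs`,
#'   all with the same slot count K.
#' @param scoring A [scoring_scheme()].
#' @return An [msa()] (dialect `ALIGNED_FASTA`), rows in input order.
#' @export
anchor_align <- function(seqs, assigns, scoring = scoring_scheme()) {
  stopifnot(length(seqs) == length(assigns), length(seqs) >= 1L)
  Ks <- vapply(assigns, function(a) length(a$slot_map), integer(1))
  if (length(unique(Ks)) != 1L) stop("assignment slot counts disagree")
  K <- Ks[1L]
  n <- length(seqs)
  segs <- matrix("", n, K + 1L)
  for (i in seq_len(n)) {
    segs[i, ] <- split_at_anchors(seqs[[i]]$residues, assigns[[i]]$slot_map)
  }
  cache <- new.env(parent = emptyenv())
  seg_aln <- vector("list", K + 1L)
  for (j in seq_len(K + 1L)) {
    seg_aln[[j]] <- center_star(segs[, j], scoring, cache)
  }
  rows <- vapply(seq_len(n), function(i) {
    pieces <- character(0)
    for (j in 0:K) {
      pieces <- c(pieces, seg_aln[[j + 1L]][i])
      if (j < K) {
        pieces <- c(pieces,
                    if (is.na(assigns[[i]]$slot_map[j + 1L])) "-" else "C")
      }
    }
    paste(pieces, collapse = "")
  }, character(1))
  msa(vapply(seqs, `[[`, character(1), "id"), rows, dialect = "ALIGNED_FASTA")
}

#' Add a sequence to an alignment by pairwise projection
#'
#' The new sequence is globally aligned to the ungapped sequence of one
#' existing row (the anchor row); the pairwise alignment is then projected
#' into alignment coordinates, opening new all-gap columns in the existing
#' rows wherever the new sequence has an insertion relative to the anchor
#' row. With `anchor_row_id = "AUTO"` the row with the highest fraction
#' identity to the new sequence (under [pairwise_global_align()]; ties ->
#' first row) is chosen.
#'
#' @param x An [msa()] (dialect `ALIGNED_FASTA`).
#' @param new A [seq_record()] to add.
#' @param anchor_row_id Row id, or `"AUTO"`.
#' @param scoring A [scoring_scheme()].
#' @return The augmented [msa()], new row appended last.
#' @export
merge_into_msa <- function(x, new, anchor_row_id = "AUTO", scoring = scoring_scheme()) {
  stopifnot(inherits(x, "msa"), inherits(new, "seq_record"))
  if (x$dialect != "ALIGNED_FASTA") stop("msa dialect must be ALIGNED_FASTA")
  if (identical(anchor_row_id, "AUTO")) {
    ident <- vapply(x$rows, function(r) {
      pa <- align_global(ungap(r), new$residues, scoring)
      aligned_fraction_identity(pa$aligned_a, pa$aligned_b)
    }, numeric(1), USE.NAMES = FALSE)
    anchor <- which.max(ident)
  } else {
    anchor <- match(anchor_row_id, x$ids)
    if (is.na(anchor)) stop("unknown anchor row id: ", sQuote(anchor_row_id))
  }
  A <- strsplit(x$rows[anchor], "")[[1]]
  u <- ungap(x$rows[anchor])
  pa <- align_global(u, new$residues, scoring)
  au <- strsplit(pa$aligned_a, "")[[1]]
  an <- strsplit(pa$aligned_b, "")[[1]]
  W <- length(A); P <- length(au)
  patch <- integer(0)     # source column in x (0 = new all-gap column)
  new_row <- character(0)
  p <- 1L
  for (c in seq_len(W)) {
    if (A[c] == "-") {
      patch <- c(patch, c); new_row <- c(new_row, "-")
      next
    }
    while (p <= P && au[p] == "-") {   # insertion before this match column
      patch <- c(patch, 0L); new_row <- c(new_row, an[p]); p <- p + 1L
    }
    patch <- c(patch, c); new_row <- c(new_row, an[p]); p <- p + 1L
  }
  while (p <= P) {                      # trailing insertions
    if (au[p] != "-") stop("internal error: unconsumed anchor residues")
    patch <- c(patch, 0L); new_row <- c(new_row, an[p]); p <- p + 1L
  }
  rows <- vapply(x$rows, function(r) {
    ch <- strsplit(r, "")[[1]]
    paste(ifelse(patch == 0L, "-", ch[pmax(patch, 1L)]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  msa(c(x$ids, new$id), c(rows, paste(new_row, collapse = "")),
      dialect = "ALIGNED_FASTA")
}
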
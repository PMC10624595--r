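## Predicted-model evaluation: coordinates, confidence, interfaces, RMSD.
##
## Predicted coordinate files store the per-residue confidence (pLDDT,
## 0-100) in the B-factor column; the companion PAE file is the standard
## n x n predicted-aligned-error matrix in JSON. Interface quality is
## scored with pDockQ (sigmoid of mean interface pLDDT x log10 contact
## count) and pDockQ2 (PAE-weighted variant, averaged over chains), both
## with the constants published by their reference implementations.

#' Read a predicted structure model from PDB
#'
#' Parses `ATOM`/`HETATM` records (fixed columns). Alternate locations are
#' resolved to the highest-occupancy conformer (ties -> altloc `A`). The
#' per-residue confidence is the CA B-factor, falling back to the mean over
#' the residue's atoms when CA is absent; values outside `[0, 100]` are a
#' parse error because the column is expected to carry pLDDT.
#'
#' @param path PDB file path (or literal text / connection).
#' @return An object of class `structure_model` with `atoms` (one row per
#'   atom) and `residues` (one row per residue, with `plddt`) data frames.
#' @export
read_structure <- function(path) {
  lines <- read_lines_any(path)
  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (length(rec) == 0L) stop("no ATOM/HETATM records found")
  f <- function(a, b) trimws(substr(rec, a, b))
  atoms <- data.frame(
    name = f(13, 16),
    altloc = f(17, 17),
    resname = f(18, 20),
    chain = f(22, 22),
    resno = suppressWarnings(as.integer(f(23, 26))),
    icode = f(27, 27),
    x = suppressWarnings(as.numeric(f(31, 38))),
    y = suppressWarnings(as.numeric(f(39, 46))),
    z = suppressWarnings(as.numeric(f(47, 54))),
    occ = suppressWarnings(as.numeric(f(55, 60))),
    b = suppressWarnings(as.numeric(f(61, 66))),
    element = toupper(f(77, 78)),
    stringsAsFactors = FALSE)
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z) || anyNA(atoms$resno)) {
    stop("unparseable coordinates or residue numbers in PDB input")
  }
  atoms$occ[is.na(atoms$occ)] <- 1
  atoms$b[is.na(atoms$b)] <- 0
  guess <- sub("^[0-9]*", "", atoms$name)
  atoms$element[!nzchar(atoms$element)] <- substr(guess[!nzchar(atoms$element)], 1, 1)
  # altloc: keep the highest-occupancy conformer; ties prefer 'A'/blank
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$name, sep = "\r")
  ord <- order(key, -atoms$occ, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  # restore file order of the survivors
  atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
  rownames(atoms) <- NULL
  if (any(atoms$b < 0 | atoms$b > 100)) {
    stop("B-factor outside [0, 100]: the column is expected to carry pLDDT")
  }
  rkey <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "\r")
  idx <- !duplicated(rkey)
  residues <- data.frame(
    chain = atoms$chain[idx], resno = atoms$resno[idx],
    icode = atoms$icode[idx], resname = atoms$resname[idx],
    stringsAsFactors = FALSE)
  residues$plddt <- vapply(which(idx), function(i) {
    sel <- rkey == rkey[i]
    ca <- sel & atoms$name == "CA"
    if (any(ca)) atoms$b[ca][1L] else mean(atoms$b[sel])
  }, numeric(1))
  structure(list(atoms = atoms, residues = residues), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d chains (%s), %d residues, %d atoms\n",
              length(unique(x$residues$chain)),
              paste(unique(x$residues$chain), collapse = ","),
              nrow(x$residues), nrow(x$atoms)))
  invisible(x)
}

#' Write a structure model as PDB
#'
#' @param model A `structure_model`.
#' @param path Output path or `NULL` for text.
#' @export
write_pdb <- function(model, path = NULL) {
  a <- model$atoms
  lines <- sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   seq_len(nrow(a)),
                   ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name),
                   a$altloc, a$resname, a$chain, a$resno, a$icode,
                   a$x, a$y, a$z, a$occ, a$b, a$element)
  txt <- paste0(paste(c(lines, "END"), collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(path)
}

#' Mean per-residue pLDDT
#'
#' @param model A `structure_model`.
#' @param chains Chain ids to include, or `NULL` for all.
#' @return Arithmetic mean of the per-residue confidence.
#' @export
mean_plddt <- function(model, chains = NULL) {
  r <- model$residues
  if (!is.null(chains)) r <- r[r$chain %in% chains, , drop = FALSE]
  if (nrow(r) == 0L) stop("empty chain selection")
  mean(r$plddt)
}

#' Detect disulfide bonds from SG geometry
#'
#' Candidate bonds are cysteine SG atom pairs within `cutoff`; conflicts
#' (an SG close to several partners) are resolved greedily by ascending
#' distance, each SG used at most once.
#'
#' @param model A `structure_model`.
#' @param cutoff SG-SG distance cutoff in Angstrom (default 2.5, covering
#'   the ~2.05 ideal bond plus model noise).
#' @return An object of class `ssbond_set`: a data frame with one row per
#'   bond (`chain1, resno1, icode1, chain2, resno2, icode2, distance`).
#' @export
detect_ssbonds <- function(model, cutoff = 2.5) {
  a <- model$atoms
  sg <- a[a$resname == "CYS" & a$name == "SG", , drop = FALSE]
  empty <- data.frame(chain1 = character(0), resno1 = integer(0), icode1 = character(0),
                      chain2 = character(0), resno2 = integer(0), icode2 = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  if (nrow(sg) < 2L) return(structure(empty, class = c("ssbond_set", "data.frame")))
  xyz <- as.matrix(sg[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  cand <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(structure(empty, class = c("ssbond_set", "data.frame")))
  cand <- cand[order(d[cand]), , drop = FALSE]
  used <- logical(nrow(sg))
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      chain1 = sg$chain[i], resno1 = sg$resno[i], icode1 = sg$icode[i],
      chain2 = sg$chain[j], resno2 = sg$resno[j], icode2 = sg$icode[j],
      distance = d[i, j], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  structure(out, class = c("ssbond_set", "data.frame"))
}

#' Classify disulfide connectivity against a pattern catalog
#'
#' Bonded residues are mapped to cysteine ordinals (1-based order of `C`
#' occurrence in `seq`, with the bond's residue number read as the sequence
#' position); the ordinal pair set is matched exactly against catalog
#' entries with the same cysteine count.
#'
#' @param bonds An `ssbond_set` (single chain).
#' @param seq The chain's [seq_record()].
#' @param catalog Named list of [connectivity_pattern()]s
#'   (default [connectivity_catalog()]).
#' @return `list(pattern = <name> | "NOVEL", pairs = <ordinal matrix>)`.
#' @export
classify_connectivity <- function(bonds, seq, catalog = connectivity_catalog()) {
  stopifnot(inherits(bonds, "ssbond_set"), inherits(seq, "seq_record"))
  cpos <- find_cysteines(seq)
  to_ordinal <- function(resno) {
    o <- match(resno, cpos)
    if (is.na(o)) stop(sprintf("bonded residue %d is not a cysteine in '%s'",
                               resno, seq$id))
    o
  }
  if (nrow(bonds) > 0L && length(unique(c(bonds$chain1, bonds$chain2))) > 1L) {
    stop("bonds span multiple chains; classify one chain at a time")
  }
  pairs <- if (nrow(bonds) == 0L) matrix(integer(0), ncol = 2L) else
    t(apply(cbind(vapply(bonds$resno1, to_ordinal, integer(1)),
                  vapply(bonds$resno2, to_ordinal, integer(1))), 1L, sort))
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  key <- function(p) paste(p[, 1L], p[, 2L], sep = "-", collapse = ",")
  for (pat in catalog) {
    if (pat$n_cys == length(cpos) && nrow(pat$pairs) == nrow(pairs) &&
        key(pat$pairs) == key(pairs)) {
      return(list(pattern = pat$name, pairs = pairs))
    }
  }
  list(pattern = "NOVEL", pairs = pairs)
}

heavy_atoms <- function(atoms) atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]

group_atoms <- function(model, chains) {
  a <- heavy_atoms(model$atoms)
  a[a$chain %in% chains, , drop = FALSE]
}

check_groups <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) stop("chain groups must be non-empty")
  if (length(intersect(group_a, group_b)) > 0L) stop("chain groups must be disjoint")
}

cross_dist <- function(xa, xb) {
  # |a|x|b| Euclidean distance matrix
  a2 <- rowSums(xa^2); b2 <- rowSums(xb^2)
  d2 <- outer(a2, b2, "+") - 2 * (xa %*% t(xb))
  sqrt(pmax(d2, 0))
}

#' Count interchain atomic contacts
#'
#' Heavy-atom pairs (one atom per chain group) within `cutoff`; hydrogens
#' are excluded. The contact definition is conventional, so the cutoff is
#' configurable and should be reported alongside the count.
#'
#' @param model A `structure_model`.
#' @param group_a,group_b Disjoint chain id sets.
#' @param cutoff Distance cutoff in Angstrom (default 4.5).
#' @return Integer contact count.
#' @export
interface_contacts <- function(model, group_a, group_b, cutoff = 4.5) {
  check_groups(group_a, group_b)
  aa <- group_atoms(model, group_a); ab <- group_atoms(model, group_b)
  if (nrow(aa) == 0L || nrow(ab) == 0L) return(0L)
  d <- cross_dist(as.matrix(aa[, c("x", "y", "z")]),
                  as.matrix(ab[, c("x", "y", "z")]))
  sum(d <= cutoff)
}

# representative side-chain point per residue: CB, falling back to CA
# (glycine and reduced models)
rep_points <- function(model, chains) {
  a <- model$atoms[model$atoms$chain %in% chains, , drop = FALSE]
  rkey <- paste(a$chain, a$resno, a$icode, sep = "\r")
  idx <- !duplicated(rkey)
  keys <- rkey[idx]
  pick <- vapply(keys, function(k) {
    sel <- which(rkey == k)
    cb <- sel[a$name[sel] == "CB"]
    if (length(cb)) cb[1L] else {
      ca <- sel[a$name[sel] == "CA"]
      if (length(ca)) ca[1L] else sel[1L]
    }
  }, integer(1))
  data.frame(chain = a$chain[pick], resno = a$resno[pick], icode = a$icode[pick],
             x = a$x[pick], y = a$y[pick], z = a$z[pick],
             stringsAsFactors = FALSE)
}

#' Interface residues between two chain groups
#'
#' Residues whose representative side-chain point (CB; CA for glycine or
#' reduced models) lies within `cb_cutoff` of a partner-group point. The
#' returned `pairs` data frame (row indices into `a`/`b` plus distance) is
#' the residue-pair set used by the pDockQ family of scores.
#'
#' @param model A `structure_model`.
#' @param group_a,group_b Disjoint chain id sets.
#' @param cb_cutoff Distance cutoff in Angstrom (default 8).
#' @return `list(a, b, pairs)` of data frames.
#' @export
interface_residues <- function(model, group_a, group_b, cb_cutoff = 8) {
  check_groups(group_a, group_b)
  ra <- rep_points(model, group_a); rb <- rep_points(model, group_b)
  if (nrow(ra) == 0L || nrow(rb) == 0L) {
    return(list(a = ra[0, ], b = rb[0, ], pairs = data.frame()))
  }
  d <- cross_dist(as.matrix(ra[, c("x", "y", "z")]),
                  as.matrix(rb[, c("x", "y", "z")]))
  hit <- which(d <= cb_cutoff, arr.ind = TRUE)
  pairs <- data.frame(ai = hit[, 1L], bi = hit[, 2L],
                      distance = d[hit], stringsAsFactors = FALSE)
  list(a = ra[sort(unique(pairs$ai)), , drop = FALSE],
       b = rb[sort(unique(pairs$bi)), , drop = FALSE],
       pairs = pairs)
}

#' Sigmoid constants for pDockQ
#'
#' Defaults are the values published with the reference implementation:
#' `0.724 / (1 + exp(-0.052 (x - 152.611))) + 0.018`.
#' @param L,x0,k,b Sigmoid parameters.
#' @return Named list.
#' @export
pdockq_constants <- function(L = 0.724, x0 = 152.611, k = 0.052, b = 0.018) {
  list(L = L, x0 = x0, k = k, b = b)
}

#' Sigmoid constants for pDockQ2
#'
#' Defaults from the reference pDockQ2 script:
#' `1.31 / (1 + exp(-0.075 (x - 84.733))) + 0.005`.
#' @param L,x0,k,b Sigmoid parameters.
#' @return Named list.
#' @export
pdockq2_constants <- function(L = 1.31, x0 = 84.733, k = 0.075, b = 0.005) {
  list(L = L, x0 = x0, k = k, b = b)
}

sigmoid_score <- function(x, const) const$L / (1 + exp(-const$k * (x - const$x0))) + const$b

residue_key <- function(df) paste(df$chain, df$resno, df$icode, sep = "\r")

residue_plddt <- function(model, keys) {
  r <- model$residues
  r$plddt[match(keys, residue_key(r))]
}

#' pDockQ interface confidence
#'
#' `x = (mean pLDDT over interface residues) * log10(number of interface
#' residue pairs)` with interface pairs defined by the representative-point
#' cutoff of [interface_residues()] (8 Angstrom, the reference convention);
#' the score is `L / (1 + exp(-k (x - x0))) + b`. With zero contacts the
#' score is the sigmoid floor `b`.
#'
#' @param model A `structure_model` with at least two chains.
#' @param group_a,group_b Chain groups; default first chain vs the rest.
#' @param cutoff Interface residue-pair cutoff (default 8).
#' @param constants See [pdockq_constants()].
#' @return The pDockQ score (scalar in `(0, 1)`).
#' @export
pdockq <- function(model, group_a = NULL, group_b = NULL, cutoff = 8,
                   constants = pdockq_constants()) {
  ch <- unique(model$residues$chain)
  if (length(ch) < 2L) stop("pDockQ requires at least two chains")
  if (is.null(group_a)) group_a <- ch[1L]
  if (is.null(group_b)) group_b <- setdiff(ch, group_a)
  ir <- interface_residues(model, group_a, group_b, cb_cutoff = cutoff)
  n_contacts <- nrow(ir$pairs)
  if (n_contacts == 0L) return(constants$b)
  keys <- c(residue_key(ir$a), residue_key(ir$b))
  x <- mean(residue_plddt(model, keys)) * log10(n_contacts)
  sigmoid_score(x, constants)
}

#' Predicted-aligned-error matrix
#'
#' @param matrix n x n non-negative matrix (Angstrom), n = residue count.
#' @param chain_spans Named list mapping chain id to its residue index
#'   range (integer vector) in matrix order.
#' @return An object of class `pae_matrix`.
#' @export
pae_matrix <- function(matrix, chain_spans) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop("PAE matrix must be square")
  if (any(matrix < 0)) stop("PAE values must be non-negative")
  idx <- sort(unlist(chain_spans, use.names = FALSE))
  if (!identical(idx, seq_len(nrow(matrix)))) {
    stop("chain spans must partition 1..n of the PAE matrix")
  }
  structure(list(matrix = matrix, chain_spans = chain_spans), class = "pae_matrix")
}

#' Read a PAE matrix in the standard AlphaFold JSON layout
#'
#' Accepts both the bare object and the one-element-array wrapping, keyed
#' `predicted_aligned_error` (or legacy `pae`). Chain spans are taken from
#' the companion model's residue order.
#'
#' @param path JSON file path.
#' @param model The companion `structure_model` (for chain spans).
#' @return A [pae_matrix()].
#' @export
read_pae <- function(path, model) {
  x <- jsonlite::fromJSON(path)
  if (is.data.frame(x)) x <- as.list(x[1L, ])
  m <- x[["predicted_aligned_error"]]
  if (is.null(m)) m <- x[["pae"]]
  if (is.list(m) && !is.matrix(m)) m <- m[[1L]]
  if (is.null(m)) stop("no predicted_aligned_error field in PAE file")
  m <- as.matrix(m)
  r <- model$residues
  spans <- split(seq_len(nrow(r)), r$chain)
  if (nrow(m) != nrow(r)) {
    stop(sprintf("PAE dimension (%d) does not match the model residue count (%d)",
                 nrow(m), nrow(r)))
  }
  pae_matrix(m, spans)
}

#' Write a PAE matrix in the AlphaFold JSON layout
#'
#' @param pae A [pae_matrix()] or plain matrix.
#' @param path Output path.
#' @export
write_pae <- function(pae, path) {
  m <- if (inherits(pae, "pae_matrix")) pae$matrix else as.matrix(pae)
  obj <- list(list(predicted_aligned_error = m,
                   max_predicted_aligned_error = max(m)))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' pDockQ2: PAE-weighted interface confidence, averaged over chains
#'
#' For each chain i, `x_i = (mean pLDDT over chain-i interface residues) *
#' mean over its interchain interface residue pairs of
#' `1 / (1 + (PAE_ij / d0)^2)` with `d0 = 10`; the per-chain score is the
#' sigmoid of `x_i` (see [pdockq2_constants()]) and the model score is the
#' arithmetic mean over chains.
#'
#' @param model A `structure_model` with at least two chains.
#' @param pae A [pae_matrix()] matching the model.
#' @param cutoff Interface residue-pair cutoff (default 8).
#' @param d0 PAE damping scale in Angstrom (default 10).
#' @param constants See [pdockq2_constants()].
#' @return `list(per_chain = named numeric, mean = scalar)`.
#' @export
pdockq2 <- function(model, pae, cutoff = 8, d0 = 10,
                    constants = pdockq2_constants()) {
  stopifnot(inherits(pae, "pae_matrix"))
  r <- model$residues
  ch <- unique(r$chain)
  if (length(ch) < 2L) stop("pDockQ2 requires at least two chains")
  if (nrow(pae$matrix) != nrow(r)) stop("PAE dimensions do not match the model")
  rk <- residue_key(r)
  per_chain <- vapply(ch, function(c) {
    ir <- interface_residues(model, c, setdiff(ch, c), cb_cutoff = cutoff)
    if (nrow(ir$pairs) == 0L) stop("chain ", c, " has no interface")
    gi <- match(residue_key(ir$a)[ir$pairs$ai], rk)   # chain-c residue index
    gj <- match(residue_key(ir$b)[ir$pairs$bi], rk)   # partner residue index
    pae_term <- mean(1 / (1 + (pae$matrix[cbind(gi, gj)] / d0)^2))
    x <- mean(residue_plddt(model, residue_key(ir$a))) * pae_term
    sigmoid_score(x, constants)
  }, numeric(1))
  names(per_chain) <- ch
  list(per_chain = per_chain, mean = mean(per_chain))
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares superposition of `moving` onto `fixed` with a proper
#' rotation (reflections excluded).
#'
#' @param moving,fixed n x 3 coordinate matrices, n >= 3.
#' @return `list(rotation, translation, rmsd)`; `fitted = moving %*%
#'   t(rotation) + translation` (row-wise).
#' @export
kabsch_superpose <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed)) stop("point sets must have equal cardinality")
  if (nrow(moving) < 3L) stop("at least 3 points are required")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  P <- sweep(moving, 2L, cm); Q <- sweep(fixed, 2L, cf)
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = cf - as.vector(R %*% cm), rmsd = rmsd)
}

chain_atom_coords <- function(model, chain, atom = "CA") {
  a <- model$atoms
  a <- a[a$chain == chain & a$name == atom, , drop = FALSE]
  a[order(a$resno, a$icode), , drop = FALSE]
}

#' RMSD of a model to a reference after joint superposition
#'
#' CA atoms of all mapped chains are pooled into a single Kabsch
#' superposition (residues matched by author numbering and insertion code,
#' common residues only); the global RMSD is returned. Symmetric complexes
#' (two receptor plus two ligand copies) make the chain pairing ambiguous:
#' pass several candidate maps and the minimum over them is returned.
#'
#' @param model,reference `structure_model` objects.
#' @param chain_map Named character vector mapping model chains to
#'   reference chains, or a list of such candidate maps.
#' @param atom Atom selection (default `"CA"`).
#' @return RMSD in Angstrom (minimum over candidate maps).
#' @export
rmsd_to_reference <- function(model, reference, chain_map, atom = "CA") {
  maps <- if (is.list(chain_map)) chain_map else list(chain_map)
  one <- function(cm) {
    mov <- NULL; fix <- NULL
    for (mc in names(cm)) {
      am <- chain_atom_coords(model, mc, atom)
      ar <- chain_atom_coords(reference, cm[[mc]], atom)
      keys <- intersect(paste(am$resno, am$icode), paste(ar$resno, ar$icode))
      if (length(keys) == 0L) next
      mov <- rbind(mov, as.matrix(am[match(keys, paste(am$resno, am$icode)),
                                     c("x", "y", "z")]))
      fix <- rbind(fix, as.matrix(ar[match(keys, paste(ar$resno, ar$icode)),
                                     c("x", "y", "z")]))
    }
    if (is.null(mov) || nrow(mov) < 3L) stop("empty residue intersection under the chain map")
    kabsch_superpose(mov, fix)$rmsd
  }
  min(vapply(maps, one, numeric(1)))
}

#' Rank models by mean pLDDT
#'
#' @param models List of `structure_model` objects.
#' @return The list reordered by descending [mean_plddt()] (stable ties),
#'   with the scores attached as attribute `mean_plddt`.
#' @export
rank_models <- function(models) {
  stopifnot(length(models) >= 1L)
  scores <- vapply(models, mean_plddt, numeric(1))
  ord <- order(-scores)   # order() is stable: ties keep input order
  out <- models[ord]
  attr(out, "mean_plddt") <- scores[ord]
  out
}

#' Per-model evaluation report
#'
#' Convenience aggregator: mean pLDDT always; interface scores only when
#' the model has two or more chains; pDockQ2 only when a PAE matrix is
#' given; RMSD only when a reference is given.
#'
#' @param model A `structure_model`.
#' @param pae Optional [pae_matrix()].
#' @param reference Optional reference `structure_model`.
#' @param chain_map Chain map(s) for [rmsd_to_reference()].
#' @param group_a,group_b Chain groups for the interface scores (default
#'   first chain vs the rest).
#' @param contact_cutoff Heavy-atom contact cutoff (default 4.5).
#' @return An object of class `eval_scores` (a named list).
#' @export
eval_scores <- function(model, pae = NULL, reference = NULL, chain_map = NULL,
                        group_a = NULL, group_b = NULL, contact_cutoff = 4.5) {
  ch <- unique(model$residues$chain)
  if (is.null(group_a)) group_a <- ch[1L]
  if (is.null(group_b)) group_b <- setdiff(ch, group_a)
  out <- list(mean_plddt = mean_plddt(model))
  if (length(ch) >= 2L) {
    out$contacts <- interface_contacts(model, group_a, group_b, cutoff = contact_cutoff)
    out$contact_cutoff <- contact_cutoff
    out$pdockq <- pdockq(model, group_a, group_b)
    if (!is.null(pae)) {
      p2 <- pdockq2(model, pae)
      out$pdockq2_per_chain <- p2$per_chain
      out$pdockq2_mean <- p2$mean
    }
  }
  if (!is.null(reference)) {
    out$rmsd <- rmsd_to_reference(model, reference, chain_map)
  }
  structure(out, class = "eval_scores")
}
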
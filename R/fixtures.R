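## Synthetic fixtures: cysteine-rich sequence families and toy dimer
## structures with planted, exactly recoverable properties.
##
## The family generator emulates the real input of the pipeline - a set of
## short (~60-70 aa) defensin-like ligand sequences sharing a conserved
## cysteine scaffold, diverged in the inter-cysteine segments - and returns
## the ground-truth anchor assignments alongside the sequences. The toy
## complex generator plants disulfide SG pairs at 2.05 A, interface atom
## pairs at 3.5 A, and keeps every other intergroup distance >= 6 A, so all
## evaluation operations have exact expected values by construction.
## Randomness uses R's default Mersenne-Twister generator through
## `set.seed`, so fixtures are byte-reproducible across platforms.

SEG_LETTERS <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "C")

#' Generate a synthetic cysteine-rich sequence family
#'
#' Sequences descend from a common ancestor with exactly `n_cys` cysteines;
#' substitutions and single-residue indels are confined to the
#' inter-cysteine segments (cysteines never mutate), so every sequence
#' keeps exactly `n_cys` cysteines and the returned anchor assignments are
#' ground truth. The first sequence is the unmutated ancestor (the query).
#'
#' Defaults emulate the field's real-world regime: families of 98 ligand
#' sequences of roughly 60-70 residues with 8 cysteines.
#'
#' @param n_sequences Number of sequences (default 98).
#' @param n_cys Cysteines per sequence (default 8).
#' @param seg_min,seg_max Ancestral inter-cysteine segment length range
#'   (default 4-8).
#' @param subst_rate Per-site substitution probability (default 0.1).
#' @param indel_rate Per-site indel probability, split evenly between
#'   deletion and insertion (default 0.05).
#' @param seed Random seed.
#' @param id_prefix Sequence id prefix.
#' @return `list(sequences = list of [seq_record()], assignments = list of
#'   [anchor_assignment()])`.
#' @export
gen_cysrich_family <- function(n_sequences = 98L, n_cys = 8L,
                               seg_min = 4L, seg_max = 8L,
                               subst_rate = 0.1, indel_rate = 0.05,
                               seed = 1L, id_prefix = "sp11_") {
  if (subst_rate < 0 || subst_rate >= 1 || indel_rate < 0 || indel_rate >= 1) {
    stop("rates must lie in [0, 1)")
  }
  if (seg_min > seg_max || seg_min < 0L) stop("need 0 <= seg_min <= seg_max")
  if (seg_max < 1L && indel_rate > 0) {
    stop("infeasible spec: zero-length segments cannot host indels")
  }
  stopifnot(n_sequences >= 1L, n_cys >= 1L)
  set.seed(seed)
  anc_segs <- vapply(seq_len(n_cys + 1L), function(i) {
    len <- sample(seg_min:seg_max, 1L)
    paste(sample(SEG_LETTERS, len, replace = TRUE), collapse = "")
  }, character(1))
  assemble <- function(segs) {
    paste0(paste(segs, collapse = "C"))
  }
  mutate_segment <- function(s) {
    chars <- strsplit(s, "")[[1]]
    out <- character(0)
    for (ch in chars) {
      if (stats::runif(1) < subst_rate) ch <- sample(setdiff(SEG_LETTERS, ch), 1L)
      if (stats::runif(1) >= indel_rate / 2) out <- c(out, ch)   # else deleted
      if (stats::runif(1) < indel_rate / 2) out <- c(out, sample(SEG_LETTERS, 1L))
    }
    paste(out, collapse = "")
  }
  seqs <- vector("list", n_sequences)
  assigns <- vector("list", n_sequences)
  for (i in seq_len(n_sequences)) {
    segs <- if (i == 1L) anc_segs else vapply(anc_segs, mutate_segment, character(1))
    id <- sprintf("%s%03d", id_prefix, i)
    seqs[[i]] <- seq_record(id, assemble(segs))
    assigns[[i]] <- anchor_assignment(id, seq_len(n_cys))
  }
  list(sequences = seqs, assignments = assigns)
}

#' Remove one anchor cysteine from a family member
#'
#' Models the naturally occurring 7-cysteine member of an 8-cysteine
#' family: the cysteine filling `slot` is deleted from sequence `index`,
#' its assignment slot becomes absent, and later slots are renumbered to
#' the remaining cysteine occurrences.
#'
#' @param family Output of [gen_cysrich_family()].
#' @param index Sequence index to modify.
#' @param slot Anchor slot to vacate.
#' @return The modified family list.
#' @export
drop_anchor <- function(family, index, slot) {
  s <- family$sequences[[index]]
  a <- family$assignments[[index]]
  ci <- a$slot_map[slot]
  if (is.na(ci)) stop("slot ", slot, " is already absent")
  pos <- find_cysteines(s)[ci]
  res <- paste0(substr(s$residues, 1L, pos - 1L),
                substr(s$residues, pos + 1L, nchar(s$residues)))
  new_map <- a$slot_map
  new_map[slot] <- NA_integer_
  later <- !is.na(new_map) & new_map > ci
  new_map[later] <- new_map[later] - 1L
  family$sequences[[index]] <- seq_record(s$id, res, s$description)
  family$assignments[[index]] <- anchor_assignment(a$sequence_id, new_map)
  family
}

#' Generate a toy receptor-ligand complex with planted properties
#'
#' Chain A (receptor) and chain B (ligand) are laid out on well-separated
#' lines; exactly `n_interface` chain-B residues are moved so their CA sits
#' 3.5 A from the matching chain-A CA, each planted disulfide ordinal pair
#' gets SG atoms 2.05 A apart, and every other intergroup atom distance is
#' >= 6 A. B-factors carry the requested pLDDT. The PAE matrix is 1 A
#' within chains (0 on the diagonal) and `interface_pae` between chains.
#'
#' Ligand cysteines occupy the last `n_cys` positions of chain B, where
#' `n_cys` is taken from the largest ordinal in `ss_pairs` (or given
#' explicitly); all other residues are glycine.
#'
#' @param chain_len_a,chain_len_b Residues per chain (defaults 12, 16).
#' @param n_interface Planted interface residue-pair count (default 3).
#' @param ss_pairs Two-column matrix of disulfide ordinal pairs planted in
#'   chain B (default the DEF8 pattern).
#' @param n_cys Cysteine count in chain B (default `max(ss_pairs)`).
#' @param plddt Uniform value or per-residue vector of length
#'   `chain_len_a + chain_len_b` (default 85).
#' @param interface_pae Interchain PAE value in Angstrom (default 10).
#' @param seed Random seed (reserved for future jitter; geometry is
#'   deterministic).
#' @return `list(model = structure_model, pae = pae_matrix, ligand_seq =
#'   seq_record, ss_pairs, n_interface)`.
#' @export
gen_toy_complex <- function(chain_len_a = 12L, chain_len_b = 16L,
                            n_interface = 3L,
                            ss_pairs = connectivity_catalog()$DEF8$pairs,
                            n_cys = max(ss_pairs, 0L),
                            plddt = 85, interface_pae = 10, seed = 1L) {
  set.seed(seed)
  ss_pairs <- if (length(ss_pairs)) matrix(as.integer(ss_pairs), ncol = 2L) else
    matrix(integer(0), ncol = 2L)
  if (n_cys > 0L && length(ss_pairs) && max(ss_pairs) > n_cys) {
    stop("ss_pairs ordinals exceed n_cys")
  }
  if (chain_len_b < n_interface + n_cys || chain_len_a < n_interface) {
    stop("geometric infeasibility: chains too short for the planted features")
  }
  n_total <- chain_len_a + chain_len_b
  plddt <- if (length(plddt) == 1L) rep(plddt, n_total) else plddt
  if (length(plddt) != n_total) stop("plddt must be scalar or one value per residue")
  if (any(plddt < 0 | plddt > 100)) stop("plddt must lie in [0, 100]")
  cys_pos <- if (n_cys > 0L) (chain_len_b - n_cys + 1L):chain_len_b else integer(0)
  atom <- function(name, resname, chain, resno, x, y, z, b, element) {
    data.frame(name = name, altloc = "", resname = resname, chain = chain,
               resno = resno, icode = "", x = x, y = y, z = z,
               occ = 1, b = b, element = element, stringsAsFactors = FALSE)
  }
  rows <- list()
  for (i in seq_len(chain_len_a)) {
    rows[[length(rows) + 1L]] <-
      atom("CA", "GLY", "A", i, 10 * i, 0, 0, plddt[i], "C")
  }
  sg_xyz <- matrix(NA_real_, n_cys, 3L)
  if (n_cys > 0L) {
    for (c in seq_len(n_cys)) sg_xyz[c, ] <- c(10 * cys_pos[c], 100, 2.0)
    if (nrow(ss_pairs) > 0L) {
      for (k in seq_len(nrow(ss_pairs))) {
        p <- ss_pairs[k, 1L]; q <- ss_pairs[k, 2L]
        sg_xyz[p, ] <- c(10 * cys_pos[p], 100, 2.0)
        sg_xyz[q, ] <- c(10 * cys_pos[p], 100, 4.05)
      }
    }
  }
  for (j in seq_len(chain_len_b)) {
    is_cys <- j %in% cys_pos
    ca_y <- if (j <= n_interface) 3.5 else 100
    b <- plddt[chain_len_a + j]
    rows[[length(rows) + 1L]] <-
      atom("CA", if (is_cys) "CYS" else "GLY", "B", j, 10 * j, ca_y, 0, b, "C")
    if (is_cys) {
      c <- match(j, cys_pos)
      rows[[length(rows) + 1L]] <-
        atom("SG", "CYS", "B", j, sg_xyz[c, 1L], sg_xyz[c, 2L], sg_xyz[c, 3L], b, "S")
    }
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  rkey <- paste(atoms$chain, atoms$resno, sep = "\r")
  idx <- !duplicated(rkey)
  residues <- data.frame(chain = atoms$chain[idx], resno = atoms$resno[idx],
                         icode = atoms$icode[idx], resname = atoms$resname[idx],
                         plddt = atoms$b[idx], stringsAsFactors = FALSE)
  model <- structure(list(atoms = atoms, residues = residues),
                     class = "structure_model")
  pae_m <- matrix(1, n_total, n_total)
  diag(pae_m) <- 0
  pae_m[seq_len(chain_len_a), chain_len_a + seq_len(chain_len_b)] <- interface_pae
  pae_m[chain_len_a + seq_len(chain_len_b), seq_len(chain_len_a)] <- interface_pae
  pae <- pae_matrix(pae_m, list(A = seq_len(chain_len_a),
                                B = chain_len_a + seq_len(chain_len_b)))
  lig_res <- ifelse(seq_len(chain_len_b) %in% cys_pos, "C", "G")
  list(model = model, pae = pae,
       ligand_seq = seq_record("toy_ligand", paste(lig_res, collapse = "")),
       ss_pairs = ss_pairs, n_interface = n_interface)
}

#' Write anchor assignments as tab-separated text
#'
#' Columns: sequence id, slot, cysteine occurrence index (`ABSENT` for a
#' vacant slot). One line per slot per sequence.
#'
#' @param assigns List of [anchor_assignment()] objects.
#' @param path Output path or `NULL` for text.
#' @export
write_assignments <- function(assigns, path = NULL) {
  lines <- unlist(lapply(assigns, function(a) {
    sprintf("%s\t%d\t%s", a$sequence_id, seq_along(a$slot_map),
            ifelse(is.na(a$slot_map), "ABSENT", as.character(a$slot_map)))
  }))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(path)
}

#' Read anchor assignments from tab-separated text
#'
#' @param path File path (format of [write_assignments()]).
#' @return Named list of [anchor_assignment()] objects.
#' @export
read_assignments <- function(path) {
  lines <- read_lines_any(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L)) stop("malformed assignment line")
  ids <- vapply(parts, `[[`, character(1), 1L)
  out <- lapply(unique(ids), function(id) {
    rows <- parts[ids == id]
    slots <- vapply(rows, function(p) as.integer(p[[2L]]), integer(1))
    vals <- vapply(rows, `[[`, character(1), 3L)
    sm <- rep(NA_integer_, max(slots))
    sm[slots] <- ifelse(vals == "ABSENT", NA_integer_,
                        suppressWarnings(as.integer(vals)))
    anchor_assignment(id, sm)
  })
  stats::setNames(out, unique(ids))
}
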
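## MSA quality metrics, paired complex-a3m assembly, refinement jobs.
##
## Complex prediction needs an a3m whose first block pairs the receptor and
## ligand rows of cognate haplotypes (so coevolutionary signal across the
## interface is visible to the predictor), followed by the two single-chain
## alignments padded with gaps on the partner side. Alignment depth is
## profiled as the per-position number of effective sequences (Neff): rows
## are weighted by 1 / (number of rows within the identity threshold) and
## the weights of rows covering each query position are summed.

#' Fraction identity between two aligned rows
#'
#' Identical non-gap columns divided by a configurable denominator:
#' `"coverage"` (default) counts columns where at least one row is non-gap,
#' `"shorter"` uses the shorter ungapped length, `"all"` the full column
#' count.
#'
#' @param row_a,row_b Equal-length aligned strings (match states).
#' @param denominator One of `"coverage"`, `"shorter"`, `"all"`.
#' @return A fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(row_a, row_b,
                              denominator = c("coverage", "shorter", "all")) {
  denominator <- match.arg(denominator)
  if (nchar(row_a) != nchar(row_b)) stop("aligned rows must have equal length")
  ca <- strsplit(row_a, "")[[1]]; cb <- strsplit(row_b, "")[[1]]
  matches <- sum(ca == cb & ca != "-")
  den <- switch(denominator,
    coverage = sum(ca != "-" | cb != "-"),
    shorter  = min(sum(ca != "-"), sum(cb != "-")),
    all      = length(ca))
  if (den == 0L) return(0)
  matches / den
}

#' Per-position number of effective sequences
#'
#' Every row s receives weight `w(s) = 1 / |{t : identity(s, t) >=
#' threshold}|` (the neighbourhood includes s itself); the Neff value of
#' query position i is the sum of `w(s)` over the rows that are non-gap at
#' that position. The profile has one value per query (first-row) position.
#' With `normalize = TRUE` values are divided by the square root of the
#' query length.
#'
#' @param x An [msa()]; the first row is the query. For the `A3M` dialect
#'   insertions are ignored (match states only).
#' @param threshold Identity threshold in (0, 1); default 0.80.
#' @param normalize Divide by `sqrt(query length)` (default `FALSE`).
#' @param denominator Identity denominator convention, see
#'   [pairwise_identity()].
#' @return An object of class `neff_profile` with fields `per_position`,
#'   `threshold`, `normalized`.
#' @export
compute_neff <- function(x, threshold = 0.8, normalize = FALSE,
                         denominator = "coverage") {
  stopifnot(inherits(x, "msa"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  rows <- if (x$dialect == "A3M") vapply(x$rows, match_states, character(1),
                                         USE.NAMES = FALSE) else x$rows
  n <- length(rows)
  C <- do.call(rbind, strsplit(rows, ""))
  nongap <- C != "-"
  nb <- integer(n)
  for (i in seq_len(n)) {
    idents <- vapply(seq_len(n), function(j) {
      if (i == j) return(1)
      pairwise_identity(rows[i], rows[j], denominator = denominator)
    }, numeric(1))
    nb[i] <- sum(idents >= threshold)
  }
  w <- 1 / nb
  qcols <- which(nongap[1L, ])
  per_pos <- vapply(qcols, function(c) sum(w[nongap[, c]]), numeric(1))
  if (normalize) per_pos <- per_pos / sqrt(length(qcols))
  structure(list(per_position = per_pos, threshold = threshold,
                 normalized = normalize),
            class = "neff_profile")
}

#' @export
print.neff_profile <- function(x, ...) {
  cat(sprintf("<neff_profile> %d positions, threshold %.2f%s; median %.2f\n",
              length(x$per_position), x$threshold,
              if (x$normalized) " (normalized)" else "",
              stats::median(x$per_position)))
  invisible(x)
}

#' Write a Neff profile as two-column tab-separated text
#'
#' @param x A `neff_profile`.
#' @param path Output path or `NULL` for text.
#' @export
write_neff_profile <- function(x, path = NULL) {
  stopifnot(inherits(x, "neff_profile"))
  lines <- sprintf("%d\t%.6g", seq_along(x$per_position), x$per_position)
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(path)
}

#' Cognate receptor-ligand haplotype pair
#'
#' @param label Haplotype name, unique within a collection.
#' @param receptor,ligand [seq_record()] objects or id strings; rows with
#'   these ids must exist in the respective single-chain alignments.
#' @return An object of class `haplotype_pair`.
#' @export
haplotype_pair <- function(label, receptor, ligand) {
  rid <- if (inherits(receptor, "seq_record")) receptor$id else receptor
  lid <- if (inherits(ligand, "seq_record")) ligand$id else ligand
  stopifnot(is.character(label), nzchar(label))
  structure(list(label = label, receptor_id = rid, ligand_id = lid),
            class = "haplotype_pair")
}

#' Read a cognate-pair manifest
#'
#' Tab-separated columns: label, receptor id, ligand id. `#` lines are
#' comments.
#'
#' @param path File path.
#' @return List of [haplotype_pair()] objects.
#' @export
read_pairs_table <- function(path) {
  lines <- read_lines_any(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  pairs <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) != 3L) stop("malformed pairs line (need label\treceptor\tligand): ",
                              sQuote(l))
    haplotype_pair(f[1L], f[2L], f[3L])
  })
  labels <- vapply(pairs, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate pair label(s): ",
                                  paste(unique(labels[duplicated(labels)]), collapse = ", "))
  pairs
}

as_query_a3m <- function(x, query_id) {
  stopifnot(inherits(x, "msa"))
  if (x$dialect == "ALIGNED_FASTA") aligned_to_a3m(x, query_id)
  else promote_query(x, query_id)
}

#' Assemble a paired complex alignment bundle
#'
#' Builds the three-block a3m used for receptor-ligand complex prediction:
#' a paired block in which each cognate pair's receptor and ligand rows are
#' horizontally concatenated (query pair first), followed by the full
#' receptor alignment padded with ligand-length gaps, then the full ligand
#' alignment padded with receptor-length gaps. Both single-chain alignments
#' are expressed in a3m form relative to the query pair's rows.
#'
#' @param pairs List of [haplotype_pair()] objects.
#' @param receptor_msa,ligand_msa Single-chain [msa()] objects
#'   (`ALIGNED_FASTA` or `A3M`) containing every pair's receptor/ligand row.
#' @param query_label The label of the query pair.
#' @return An object of class `complex_msa_bundle` with fields `header`,
#'   `paired_ids`, `paired_rows`, `receptor_block`, `ligand_block`.
#' @export
build_complex_bundle <- function(pairs, receptor_msa, ligand_msa, query_label) {
  labels <- vapply(pairs, `[[`, character(1), "label")
  qi <- match(query_label, labels)
  if (is.na(qi)) stop("query label not among pairs: ", sQuote(query_label))
  q <- pairs[[qi]]
  lookup <- function(m, id, what) {
    i <- match(id, m$ids)
    if (is.na(i)) stop(sprintf("%s id '%s' not found in its alignment", what, id))
    i
  }
  lookup(receptor_msa, q$receptor_id, "receptor")
  lookup(ligand_msa, q$ligand_id, "ligand")
  r <- as_query_a3m(receptor_msa, q$receptor_id)
  l <- as_query_a3m(ligand_msa, q$ligand_id)
  Lr <- n_match_states(r$rows[1L])
  Ll <- n_match_states(l$rows[1L])
  header <- pairing_header(c(Lr, Ll), c(1L, 1L))
  ord <- c(qi, setdiff(seq_along(pairs), qi))
  paired_rows <- vapply(ord, function(i) {
    p <- pairs[[i]]
    paste0(r$rows[lookup(r, p$receptor_id, "receptor")],
           l$rows[lookup(l, p$ligand_id, "ligand")])
  }, character(1))
  rec_block <- msa(r$ids, paste0(r$rows, strrep("-", Ll)), dialect = "A3M")
  lig_block <- msa(l$ids, paste0(strrep("-", Lr), l$rows), dialect = "A3M")
  structure(list(header = header, paired_ids = labels[ord],
                 paired_rows = paired_rows,
                 receptor_block = rec_block, ligand_block = lig_block),
            class = "complex_msa_bundle")
}

#' @export
print.complex_msa_bundle <- function(x, ...) {
  cat(sprintf("<complex_msa_bundle> %s; %d paired rows, blocks %d + %d rows\n",
              format_pairing_header(x$header), length(x$paired_rows),
              length(x$receptor_block$rows), length(x$ligand_block$rows)))
  invisible(x)
}

#' Serialize a complex bundle to the paired a3m dialect
#'
#' @param bundle A `complex_msa_bundle`.
#' @param path Output path or `NULL` for text.
#' @export
write_complex_bundle <- function(bundle, path = NULL) {
  stopifnot(inherits(bundle, "complex_msa_bundle"))
  all_ids <- c(bundle$paired_ids, bundle$receptor_block$ids, bundle$ligand_block$ids)
  all_rows <- c(bundle$paired_rows, bundle$receptor_block$rows, bundle$ligand_block$rows)
  m <- msa(all_ids, all_rows, dialect = "A3M")
  write_a3m(m, header = bundle$header, path = path)
}

#' Read a complex bundle from the paired a3m dialect
#'
#' Rows are assigned to blocks structurally: rows whose ligand half is all
#' gaps belong to the receptor block, rows whose receptor half is all gaps
#' to the ligand block, all others to the paired block. (A cognate paired
#' row never has a fully gapped half.)
#'
#' @param source File path, connection, or literal text.
#' @return A `complex_msa_bundle`.
#' @export
read_complex_bundle <- function(source) {
  parsed <- read_a3m(source, strict_ids = FALSE)
  if (is.null(parsed$header) || length(parsed$header$lengths) != 2L) {
    stop("a complex bundle requires a two-component pairing header")
  }
  Lr <- parsed$header$lengths[1L]; Ll <- parsed$header$lengths[2L]
  ms <- vapply(parsed$msa$rows, match_states, character(1), USE.NAMES = FALSE)
  rec_half <- substr(ms, 1L, Lr)
  lig_half <- substr(ms, Lr + 1L, Lr + Ll)
  is_rec <- lig_half == strrep("-", Ll)
  is_lig <- rec_half == strrep("-", Lr)
  if (any(is_rec & is_lig)) stop("all-gap row in complex bundle")
  paired <- !is_rec & !is_lig
  if (!any(paired)) stop("complex bundle has no paired rows")
  structure(list(
    header = parsed$header,
    paired_ids = parsed$msa$ids[paired],
    paired_rows = parsed$msa$rows[paired],
    receptor_block = msa(parsed$msa$ids[is_rec], parsed$msa$rows[is_rec],
                         dialect = "A3M"),
    ligand_block = msa(parsed$msa$ids[is_lig], parsed$msa$rows[is_lig],
                       dialect = "A3M")),
    class = "complex_msa_bundle")
}

#' Build a refinement job for a low-confidence query
#'
#' The refinement protocol re-predicts a query with a class-restricted
#' alignment, the best previously predicted model (highest mean pLDDT) as
#' template, and the recycle count raised to 9.
#'
#' @param query_id Query sequence id (must be a row of `class_msa`).
#' @param class_msa Class-restricted [msa()].
#' @param candidate_models `data.frame` with columns `path` and
#'   `mean_plddt`, one row per candidate template model.
#' @param recycles Recycle count (default 9).
#' @return An object of class `refinement_job`.
#' @export
make_refinement_job <- function(query_id, class_msa, candidate_models,
                                recycles = 9L) {
  stopifnot(is.data.frame(candidate_models),
            all(c("path", "mean_plddt") %in% names(candidate_models)))
  if (nrow(candidate_models) == 0L) stop("candidate model list must be non-empty")
  if (recycles < 1L) stop("recycles must be >= 1")
  best <- which.max(candidate_models$mean_plddt)   # ties -> first listed
  structure(list(query_id = query_id,
                 msa = promote_query(class_msa, query_id),
                 template_path = as.character(candidate_models$path[best]),
                 recycles = as.integer(recycles)),
            class = "refinement_job")
}

#' Write a refinement job manifest
#'
#' The alignment is written next to the manifest and referenced from it; the
#' manifest is a flat key-value text file (`query`, `msa`, `template`,
#' `recycles`) consumable by a downstream prediction wrapper.
#'
#' @param job A `refinement_job`.
#' @param msa_path Where to write the (query-promoted) alignment.
#' @param path Manifest output path or `NULL` for text.
#' @export
write_refinement_job <- function(job, msa_path, path = NULL) {
  stopifnot(inherits(job, "refinement_job"))
  if (job$msa$dialect == "A3M") write_a3m(job$msa, path = msa_path)
  else write_aligned_fasta(job$msa, path = msa_path)
  lines <- c(paste0("query\t", job$query_id),
             paste0("msa\t", msa_path),
             paste0("template\t", job$template_path),
             paste0("recycles\t", job$recycles))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(path)
}
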
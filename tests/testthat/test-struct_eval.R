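# minimal hand-built PDB text helpers
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          b = 80, occ = 1, altloc = "", element = NULL) {
  if (is.null(element)) element <- substr(name, 1, 1)
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name), altloc,
          resname, chain, resno, x, y, z, occ, b, element)
}

test_that("read_structure: representative pLDDT and validation", {
  txt <- pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0, b = 75)
  m <- read_structure(txt)
  expect_equal(m$residues$plddt, 75)

  # residue lacking CA: mean over atoms
  txt2 <- paste(pdb_atom_line(1, "N", "GLY", "A", 1, 0, 0, 0, b = 70),
                pdb_atom_line(2, "O", "GLY", "A", 1, 1, 0, 0, b = 80), sep = "\n")
  expect_equal(read_structure(txt2)$residues$plddt, 75)

  expect_error(read_structure("REMARK nothing here"), "no ATOM")
  expect_error(read_structure(pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0, b = 101)),
               "pLDDT")
})

test_that("read_structure resolves altlocs to the highest occupancy", {
  txt <- paste(
    pdb_atom_line(1, "CA", "SER", "A", 1, 0, 0, 0, b = 50, occ = 0.4, altloc = "A"),
    pdb_atom_line(2, "CA", "SER", "A", 1, 5, 0, 0, b = 90, occ = 0.6, altloc = "B"),
    sep = "\n")
  m <- read_structure(txt)
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$x, 5)
  expect_equal(m$residues$plddt, 90)
})

test_that("write_pdb round trips through read_structure", {
  toy <- gen_toy_complex(seed = 3L)
  back <- read_structure(write_pdb(toy$model))
  expect_equal(back$atoms$x, toy$model$atoms$x, tolerance = 1e-3)
  expect_equal(back$residues$plddt, toy$model$residues$plddt)
  expect_equal(back$atoms$name, toy$model$atoms$name)
})

test_that("mean_plddt over selections", {
  txt <- paste(pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0, b = 60),
               pdb_atom_line(2, "CA", "GLY", "B", 1, 9, 0, 0, b = 90), sep = "\n")
  m <- read_structure(txt)
  expect_equal(mean_plddt(m), 75)
  expect_equal(mean_plddt(m, "B"), 90)
  expect_error(mean_plddt(m, "Z"), "empty chain selection")
  # constant B-factors give the constant for any selection
  toy <- gen_toy_complex(plddt = 91.7)
  expect_equal(mean_plddt(toy$model), 91.7)
  expect_equal(mean_plddt(toy$model, "A"), 91.7)
  expect_equal(mean_plddt(toy$model, "B"), 91.7)
})

test_that("detect_ssbonds: cutoff and greedy conflict resolution", {
  sg <- function(serial, resno, x) {
    pdb_atom_line(serial, "SG", "CYS", "A", resno, x, 0, 0, element = "S")
  }
  ca <- function(serial, resno, x) pdb_atom_line(serial, "CA", "CYS", "A", resno, x, 0, 0)
  two <- read_structure(paste(ca(1, 1, 0), sg(2, 1, 0), ca(3, 2, 2), sg(4, 2, 2.05),
                              sep = "\n"))
  b <- detect_ssbonds(two)
  expect_equal(nrow(b), 1L)
  expect_equal(b$distance, 2.05)

  apart <- read_structure(paste(sg(1, 1, 0), sg(2, 2, 4.0), sep = "\n"))
  expect_equal(nrow(detect_ssbonds(apart)), 0L)

  # chain A-B at 2.0, B-C at 2.2: greedy takes A-B only
  tri <- read_structure(paste(sg(1, 1, 0), sg(2, 2, 2.0), sg(3, 3, 4.2), sep = "\n"))
  b <- detect_ssbonds(tri)
  expect_equal(nrow(b), 1L)
  expect_equal(sort(c(b$resno1, b$resno2)), c(1L, 2L))
})

test_that("planted SG geometry is recovered exactly (vs exhaustive matching)", {
  for (seed in 1:5) {
    pats <- connectivity_catalog()
    pat <- pats[[((seed - 1L) %% length(pats)) + 1L]]
    toy <- gen_toy_complex(chain_len_b = pat$n_cys + 4L, n_interface = 2L,
                           ss_pairs = pat$pairs, seed = seed)
    bonds <- detect_ssbonds(toy$model)
    got <- t(apply(cbind(bonds$resno1, bonds$resno2), 1L, sort))
    cys_pos <- sort(unique(toy$model$atoms$resno[toy$model$atoms$name == "SG"]))
    want <- t(apply(matrix(cys_pos[toy$ss_pairs], ncol = 2L), 1L, sort))
    expect_equal(got[order(got[, 1L]), , drop = FALSE],
                 want[order(want[, 1L]), , drop = FALSE])
    # exhaustive min-weight matching agrees on this geometry
    sg <- toy$model$atoms[toy$model$atoms$name == "SG", ]
    om <- oracle_sg_matching(as.matrix(sg[, c("x", "y", "z")]), 2.5)
    oracle_pairs <- t(apply(matrix(sg$resno[om], ncol = 2L), 1L, sort))
    expect_equal(oracle_pairs[order(oracle_pairs[, 1L]), , drop = FALSE],
                 want[order(want[, 1L]), , drop = FALSE])
  }
})

test_that("classify_connectivity: catalog round trip for all five patterns", {
  for (pat in connectivity_catalog()) {
    toy <- gen_toy_complex(chain_len_b = pat$n_cys + 4L, n_interface = 2L,
                           ss_pairs = pat$pairs)
    res <- classify_connectivity(detect_ssbonds(toy$model), toy$ligand_seq)
    expect_equal(res$pattern, pat$name)
  }
})

test_that("classify_connectivity flags novel patterns and non-cysteines", {
  toy <- gen_toy_complex(ss_pairs = rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8)))
  res <- classify_connectivity(detect_ssbonds(toy$model), toy$ligand_seq)
  expect_equal(res$pattern, "NOVEL")
  expect_equal(nrow(res$pairs), 4L)
  wrong_seq <- seq_record("w", strrep("G", nchar(toy$ligand_seq$residues)))
  expect_error(classify_connectivity(detect_ssbonds(toy$model), wrong_seq),
               "not a cysteine")
})

test_that("interface_contacts: examples and brute-force agreement", {
  far <- read_structure(paste(pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
                              pdb_atom_line(2, "CA", "GLY", "B", 1, 10, 0, 0),
                              sep = "\n"))
  expect_equal(interface_contacts(far, "A", "B"), 0L)
  near <- read_structure(paste(pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
                               pdb_atom_line(2, "CA", "GLY", "B", 1, 4, 0, 0),
                               sep = "\n"))
  expect_equal(interface_contacts(near, "A", "B"), 1L)
  expect_error(interface_contacts(near, "A", "A"), "disjoint")

  for (k in c(1L, 4L, 8L)) {
    toy <- gen_toy_complex(chain_len_a = 10L, chain_len_b = 18L, n_interface = k)
    expect_equal(interface_contacts(toy$model, "A", "B"), k)
    # brute-force double loop over heavy atoms
    a <- toy$model$atoms
    aa <- a[a$chain == "A" & a$element != "H", ]
    ab <- a[a$chain == "B" & a$element != "H", ]
    cnt <- 0L
    for (i in seq_len(nrow(aa))) for (j in seq_len(nrow(ab))) {
      d <- sqrt(sum((unlist(aa[i, c("x", "y", "z")]) -
                     unlist(ab[j, c("x", "y", "z")]))^2))
      if (d <= 4.5) cnt <- cnt + 1L
    }
    expect_equal(cnt, k)
  }
})

test_that("hydrogens are excluded from contacts", {
  txt <- paste(pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
               pdb_atom_line(2, "H", "GLY", "B", 1, 2, 0, 0, element = "H"),
               pdb_atom_line(3, "CA", "GLY", "B", 1, 4, 0, 0),
               sep = "\n")
  expect_equal(interface_contacts(read_structure(txt), "A", "B"), 1L)
})

test_that("interface_residues uses the CB/CA representative within 8 A", {
  toy <- gen_toy_complex(n_interface = 4L)
  ir <- interface_residues(toy$model, "A", "B")
  expect_equal(nrow(ir$pairs), 4L)
  expect_equal(sort(ir$a$resno), 1:4)
  expect_equal(sort(ir$b$resno), 1:4)
  # separated chains: empty
  far <- gen_toy_complex(n_interface = 0L)
  expect_equal(nrow(interface_residues(far$model, "A", "B")$pairs), 0L)
})

test_that("pdockq: floor, formula oracle, monotonicity", {
  const <- pdockq_constants()
  far <- gen_toy_complex(n_interface = 0L)
  expect_equal(pdockq(far$model), const$b)

  for (pl in c(60, 80, 95)) {
    k <- 5L
    toy <- gen_toy_complex(n_interface = k, plddt = pl)
    x <- pl * log10(k)     # k residue pairs, uniform interface pLDDT
    want <- const$L / (1 + exp(-const$k * (x - const$x0))) + const$b
    expect_equal(pdockq(toy$model), want, tolerance = 1e-12)
  }
  # monotone in interface pLDDT
  lo <- pdockq(gen_toy_complex(n_interface = 5L, plddt = 60)$model)
  hi <- pdockq(gen_toy_complex(n_interface = 5L, plddt = 95)$model)
  expect_gt(hi, lo)
})

test_that("pdockq2: limit cases and formula oracle", {
  const <- pdockq2_constants()
  toy0 <- gen_toy_complex(n_interface = 4L, plddt = 80, interface_pae = 0)
  p0 <- pdockq2(toy0$model, toy0$pae)
  want0 <- cysmsa:::sigmoid_score(80, const)     # PAE factor exactly 1
  expect_equal(unname(p0$per_chain), rep(want0, 2L), tolerance = 1e-12)

  toy10 <- gen_toy_complex(n_interface = 4L, plddt = 80, interface_pae = 10)
  p10 <- pdockq2(toy10$model, toy10$pae)
  want10 <- cysmsa:::sigmoid_score(40, const)    # factor 1/(1+1) = 0.5
  expect_equal(p10$mean, want10, tolerance = 1e-12)

  toyinf <- gen_toy_complex(n_interface = 4L, plddt = 80, interface_pae = 1e6)
  pinf <- pdockq2(toyinf$model, toyinf$pae)
  expect_equal(pinf$mean, cysmsa:::sigmoid_score(0, const), tolerance = 1e-6)
  expect_lt(pinf$mean, 0.01)

  # monotone non-increasing in PAE
  expect_true(p0$mean >= p10$mean && p10$mean >= pinf$mean)
  # dimension mismatch
  bad <- pae_matrix(matrix(0, 4, 4), list(A = 1:2, B = 3:4))
  expect_error(pdockq2(toy0$model, bad), "do not match")
})

test_that("PAE JSON round trip (both layouts)", {
  toy <- gen_toy_complex(chain_len_a = 3L, chain_len_b = 10L, n_interface = 1L,
                         ss_pairs = rbind(c(1, 4), c(2, 3)), interface_pae = 7)
  f <- tempfile(fileext = ".json")
  write_pae(toy$pae, f)
  back <- read_pae(f, toy$model)
  expect_equal(back$matrix, toy$pae$matrix)
  # bare-object layout
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(predicted_aligned_error = toy$pae$matrix), f2, digits = NA)
  expect_equal(read_pae(f2, toy$model)$matrix, toy$pae$matrix)
})

test_that("kabsch_superpose: exactness and rigid invariance", {
  X <- matrix(stats::rnorm(24), 8, 3)
  k <- kabsch_superpose(X, X)
  expect_equal(k$rmsd, 0, tolerance = 1e-8)
  expect_equal(k$rotation, diag(3), tolerance = 1e-8)
  # translated copy
  expect_equal(kabsch_superpose(X, sweep(X, 2, c(3, -1, 7), "+"))$rmsd, 0,
               tolerance = 1e-8)
  set.seed(31)
  for (i in 1:10) {
    R <- random_rotation()
    Y <- X %*% t(R) + matrix(rep(stats::rnorm(3), each = 8), 8, 3)
    expect_equal(kabsch_superpose(X, Y)$rmsd, 0, tolerance = 1e-8)
  }
  expect_error(kabsch_superpose(X[1:2, ], X[1:2, ]), "at least 3")
  expect_error(kabsch_superpose(X, X[1:4, ]), "equal cardinality")
})

test_that("kabsch rmsd equals brute-force minimisation on a displaced toy", {
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  Y <- X; Y[4L, ] <- Y[4L, ] + c(0.5, 0, 0)
  got <- kabsch_superpose(X, Y)$rmsd
  euler <- function(p) {
    cx <- cos(p[1]); sx <- sin(p[1]); cy <- cos(p[2]); sy <- sin(p[2])
    cz <- cos(p[3]); sz <- sin(p[3])
    matrix(c(cy * cz, sx * sy * cz - cx * sz, cx * sy * cz + sx * sz,
             cy * sz, sx * sy * sz + cx * cz, cx * sy * sz - sx * cz,
             -sy, sx * cy, cx * cy), 3, 3, byrow = TRUE)
  }
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  f <- function(p) sqrt(mean(rowSums((Xc %*% t(euler(p)) - Yc)^2)))
  set.seed(7)
  best <- min(vapply(1:25, function(i) {
    stats::optim(stats::runif(3, -pi, pi), f)$value
  }, numeric(1)))
  expect_equal(got, best, tolerance = 1e-4)
})

test_that("rmsd_to_reference: self, rigid copy, and pairing minimisation", {
  toy <- gen_toy_complex()
  m <- toy$model
  expect_equal(rmsd_to_reference(m, m, c(A = "A", B = "B")), 0, tolerance = 1e-8)
  set.seed(13)
  rot <- transform_model(m, random_rotation(), c(5, -3, 2))
  expect_equal(rmsd_to_reference(rot, m, c(A = "A", B = "B")), 0, tolerance = 1e-8)

  # symmetric-complex ambiguity: swapping equivalent chain labels must not
  # change the result when both pairings are evaluated
  swapped <- m
  swapped$atoms$chain <- chartr("AB", "BA", swapped$atoms$chain)
  swapped$residues$chain <- chartr("AB", "BA", swapped$residues$chain)
  maps <- list(c(A = "A", B = "B"), c(A = "B", B = "A"))
  expect_equal(rmsd_to_reference(swapped, m, maps), 0, tolerance = 1e-8)
  expect_error(rmsd_to_reference(m, m, c(A = "Z")), "empty residue intersection")
})

test_that("rank_models sorts by descending mean pLDDT, stable on ties", {
  mk <- function(b) read_structure(pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0, b = b))
  models <- list(mk(70), mk(90), mk(80))
  ranked <- rank_models(models)
  expect_equal(attr(ranked, "mean_plddt"), c(90, 80, 70))
  tied <- rank_models(list(mk(80), mk(80)))
  expect_identical(tied[[1L]], mk(80))
  expect_equal(attr(tied, "mean_plddt"), c(80, 80))
  single <- rank_models(models[2L])
  expect_equal(attr(single, "mean_plddt"), 90)
})

test_that("eval_scores aggregates what its inputs allow", {
  toy <- gen_toy_complex(n_interface = 3L, plddt = 88)
  es <- eval_scores(toy$model, pae = toy$pae, reference = toy$model,
                    chain_map = c(A = "A", B = "B"))
  expect_equal(es$mean_plddt, 88)
  expect_equal(es$contacts, 3L)
  expect_equal(es$rmsd, 0, tolerance = 1e-8)
  expect_true(es$pdockq > 0 && es$pdockq2_mean > 0)
})
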
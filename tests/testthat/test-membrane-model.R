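test_that("GRO and native-container round trips preserve coordinates", {
  sys <- make_multilayer(synthetic_spec(n_lipids = 60, water_per_lipid = 5,
                                        seed = 2))
  gro <- withr::local_tempfile(fileext = ".gro")
  topo_csv <- withr::local_tempfile(fileext = ".csv")
  write_gro(sys, gro)
  write.csv(as.data.frame(sys$topology), topo_csv, row.names = FALSE)
  back <- load_system(gro, topo_csv)
  expect_length(back$frames, 1)
  expect_equal(nrow(back$topology), nrow(sys$topology))
  expect_lt(max(abs(back$frames[[1]]$coords - sys$frames[[1]]$coords)), 5e-4 + 1e-9)

  scm <- withr::local_tempfile(fileext = ".scm")
  write_system(sys, scm)
  back2 <- load_system(scm)
  expect_lt(max(abs(back2$frames[[1]]$coords - sys$frames[[1]]$coords)), 1e-6)
  expect_identical(back2$topology$bead_name, sys$topology$bead_name)
})

test_that("tiny PDB input loads with Angstrom-to-nm conversion", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1  100.000  100.000  100.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  C1  LIG A   1      10.000  20.000  30.000  1.00  0.00           C",
    "ATOM      2  C2  LIG A   1      11.000  20.000  30.000  1.00  0.00           C",
    "ATOM      3  C3  LIG A   1      12.000  20.000  30.000  1.00  0.00           C",
    "END"), pdb)
  topo_csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(particle_index = 0:2, lipid_id = 1, species = "FFA",
                       chain_role = c("none", "fatty", "fatty"),
                       bead_name = c("HEAD", "F1", "F2"), mass = 14,
                       is_head = c(TRUE, FALSE, FALSE)),
            topo_csv, row.names = FALSE)
  sys <- load_system(pdb, topo_csv)
  expect_equal(sys$frames[[1]]$coords[1, ], c(1, 2, 3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sys$frames[[1]]$box, c(10, 10, 10))
})

test_that("particle-count mismatch and unknown species are hard errors", {
  gro <- withr::local_tempfile(fileext = ".gro")
  co <- matrix(runif(18), ncol = 3)
  writeLines(c("toy", "    6",
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "FFA", "F1", 1:6,
                       co[, 1], co[, 2], co[, 3]),
               "   5.00000   5.00000   5.00000"), gro)
  topo5 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(particle_index = 0:4, lipid_id = 1, species = "FFA",
                       chain_role = "fatty", bead_name = paste0("F", 1:5),
                       mass = 72, is_head = c(TRUE, rep(FALSE, 4))),
            topo5, row.names = FALSE)
  expect_error(load_system(gro, topo5), "5 vs 6")

  topo_bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(particle_index = 0:5, lipid_id = 1, species = "LIPIDX",
                       chain_role = "fatty", bead_name = paste0("F", 1:6),
                       mass = 72, is_head = c(TRUE, rep(FALSE, 5))),
            topo_bad, row.names = FALSE)
  expect_error(load_system(gro, topo_bad), "unknown species")
})

test_that("leaflet detection finds constructed head planes", {
  planes <- c(0.5, 5.7, 6.5, 11.7, 12.5, 17.7)
  sys <- toy_ffa_stack(planes)
  lf <- assign_leaflets(sys$frame, sys$topology)
  expect_equal(lf$n_leaflets, 6L)
  expect_equal(lf$peak_z, planes, tolerance = 0.06)
  expect_equal(lf$central_bilayer, c(3L, 4L))

  one <- toy_ffa_stack(c(0.5, 5.5))
  lf2 <- assign_leaflets(one$frame, one$topology, n_leaflets = 2)
  expect_equal(lf2$peak_z, c(0.5, 5.5), tolerance = 0.06)

  flat <- toy_ffa_stack(c(3, 3.0001), per_plane = 30, jitter = 0)
  expect_error(assign_leaflets(flat$frame, flat$topology, n_leaflets = 2),
               "leaflet detection failed")
})

test_that("leaflet assignment is invariant to particle order", {
  sys <- toy_ffa_stack(c(0.5, 5.7, 6.5, 11.7, 12.5, 17.7), seed = 9)
  lf <- assign_leaflets(sys$frame, sys$topology)
  set.seed(1)
  perm <- sample(nrow(sys$topology))
  topo2 <- sys$topology[perm, ]
  fr2 <- sc_frame(sys$frame$coords[perm, ], sys$frame$box)
  lf2 <- assign_leaflets(fr2, topo2)
  ids <- names(lf$lipid_leaflet)
  expect_identical(lf$lipid_leaflet[ids], lf2$lipid_leaflet[ids])
})

test_that("CER conformer classification follows terminal-bead leaflets", {
  planes <- c(0.5, 5.7, 6.5, 11.7, 12.5, 17.7)
  base <- toy_ffa_stack(planes)
  # hairpin: head at the lower central plane, both chains ascending
  hp <- add_cer(base, head_z = 6.5, acyl_z = c(7.0, 7.8, 8.6),
                sph_z = c(7.0, 7.6, 8.2))
  lf <- assign_leaflets(hp$frame, hp$topology)
  expect_identical(classify_cer_conformer(hp$cer_id, hp$frame, hp$topology, lf),
                   "hairpin")
  # extended: acyl ascends into leaflet 3, sphingosine descends into leaflet 2
  ext <- add_cer(base, head_z = 6.5, acyl_z = c(7.0, 7.8, 8.6),
                 sph_z = c(6.0, 5.4, 4.8))
  lf <- assign_leaflets(ext$frame, ext$topology)
  expect_identical(classify_cer_conformer(ext$cer_id, ext$frame, ext$topology,
                                          lf), "extended")
  ti <- tail_instances(ext$frame, ext$topology, lf)
  cer_tails <- ti[ti$lipid_id == ext$cer_id, ]
  expect_setequal(cer_tails$leaflet, c(2L, 3L))
  expect_true(all(cer_tails$conformer == "extended"))
})

test_that("classifier recovers generator conformer labels on a full stack", {
  sys <- make_multilayer(synthetic_spec(n_lipids = 2000, seed = 17))
  gt <- ground_truth(sys)
  lf <- assign_leaflets(sys$frames[[1]], sys$topology)
  ti <- tail_instances(sys$frames[[1]], sys$topology, lf)
  pred <- tapply(ti$conformer[ti$tail_type %in% c("CER_acyl", "CER_sph")],
                 ti$lipid_id[ti$tail_type %in% c("CER_acyl", "CER_sph")],
                 function(x) x[1])
  cer <- gt$lipids[gt$lipids$species == "CER_NS", ]
  truth <- ifelse(cer$conformer == "not_applicable", "hairpin", cer$conformer)
  expect_identical(as.vector(pred[as.character(cer$lipid_id)]), truth)
  eligible <- cer$leaflet > 1 & cer$leaflet < 6
  frac <- mean(pred[as.character(cer$lipid_id[eligible])] == "extended")
  expect_equal(frac, 0.35, tolerance = 0.02 / 0.35)
})

test_that("tail center of mass is mass weighted and excludes head beads", {
  expect_equal(tail_com(rbind(c(0, 0, 1), c(0, 0, 3)), c(1, 1)), c(0, 0, 2))
  expect_equal(tail_com(rbind(c(0, 0, 0), c(3, 0, 0)), c(2, 1)), c(1, 0, 0))
  expect_error(tail_com(rbind(c(0, 0, 0)), 0), "zero total mass")
  # CHOL com from tail_instances ignores the CHEAD bead
  topo <- sc_topology(data.frame(
    particle_index = 0:2, lipid_id = 1, species = "CHOL",
    chain_role = c("none", "sterol", "sterol"),
    bead_name = c("CHEAD", "C1", "C2"), mass = 72,
    is_head = c(TRUE, FALSE, FALSE)))
  fr <- sc_frame(rbind(c(5, 5, 9), c(5, 5, 1), c(5, 5, 3)), c(10, 10, 10))
  lf <- list(boundaries = 5, peak_z = c(2, 8),
             lipid_leaflet = c(`1` = 1L), n_leaflets = 2L,
             central_bilayer = c(1L, 2L))
  class(lf) <- "sc_leaflets"
  ti <- tail_instances(fr, topo, lf)
  expect_equal(ti$z, 2)   # mean of tail beads only, not the CHEAD at 9
})

test_that("periodic in-plane distance uses the minimum image", {
  expect_equal(pbc_xy_distance(c(0, 0), c(9.5, 0), c(10, 10)), 0.5)
  expect_equal(pbc_xy_distance(c(2, 3), c(2, 3), c(10, 10)), 0)
  expect_equal(pbc_xy_distance(c(1, 1), c(4, 5), c(100, 100)), 5)
})
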
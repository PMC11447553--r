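# In-code fixtures: tiny membrane systems built bead by bead.

# A stack of single-chain FFA lipids with head planes at `planes` (nm);
# enough structure for leaflet detection and toy classification tests.
toy_ffa_stack <- function(planes, per_plane = 20, jitter = 0.01, seed = 42,
                          box_xy = 10) {
  set.seed(seed)
  rows <- list()
  co <- list()
  lip <- 0L
  for (p in seq_along(planes)) {
    sigma <- if (p %% 2 == 1) 1 else -1   # odd planes: tails point up
    for (i in seq_len(per_plane)) {
      lip <- lip + 1L
      x <- runif(1, 0, box_xy); y <- runif(1, 0, box_xy)
      zs <- planes[p] + rnorm(1, 0, jitter)
      co[[length(co) + 1L]] <- rbind(
        c(x, y, zs),
        c(x, y, zs + sigma * 0.5),
        c(x, y, zs + sigma * 1.0),
        c(x, y, zs + sigma * 1.5))
      rows[[length(rows) + 1L]] <- data.frame(
        lipid_id = lip, species = "FFA",
        chain_role = c("none", "fatty", "fatty", "fatty"),
        bead_name = c("HEAD", "F1", "F2", "F3"),
        mass = 72, is_head = c(TRUE, FALSE, FALSE, FALSE))
    }
  }
  df <- do.call(rbind, rows)
  df <- cbind(particle_index = seq_len(nrow(df)) - 1L, df)
  list(topology = sc_topology(df),
       frame = sc_frame(do.call(rbind, co),
                        c(box_xy, box_xy, max(planes) + 3)))
}

# Append one CER NS lipid (4 head beads + 3-bead acyl and sphingosine
# chains at given bead z sequences) to an existing toy system.
add_cer <- function(sys, head_z, acyl_z, sph_z, x = 5, y = 5) {
  topo <- as.data.frame(sys$topology)
  lip <- max(topo$lipid_id) + 1L
  n0 <- nrow(topo)
  beads <- data.frame(
    particle_index = n0 + seq_len(4 + length(acyl_z) + length(sph_z)) - 1L,
    lipid_id = lip, species = "CER_NS",
    chain_role = c(rep("none", 4), rep("acyl", length(acyl_z)),
                   rep("sphingosine", length(sph_z))),
    bead_name = c("MHEAD2", "AMIDE", "OH1", "OH2",
                  paste0("A", seq_along(acyl_z)),
                  paste0("S", seq_along(sph_z))),
    mass = 72,
    is_head = c(rep(TRUE, 4), rep(FALSE, length(acyl_z) + length(sph_z))))
  co <- rbind(matrix(c(x, y, head_z), 4, 3, byrow = TRUE),
              cbind(x, y, acyl_z), cbind(x, y, sph_z))
  list(topology = sc_topology(rbind(topo, beads)),
       frame = sc_frame(rbind(sys$frame$coords, co), sys$frame$box),
       cer_id = lip)
}

# Straight chains parallel to `axis`, for order-parameter constructions.
straight_chain_system <- function(n_chains = 10, n_beads = 16, axis = c(0, 0, 1),
                                  spacing = 0.127, seed = 1, species = "FFA") {
  set.seed(seed)
  axis <- axis / sqrt(sum(axis^2))
  co <- list(); rows <- list()
  for (i in seq_len(n_chains)) {
    x0 <- c(runif(1, 0, 5), runif(1, 0, 5), runif(1, 0, 2))
    co[[i]] <- matrix(rep(x0, each = n_beads), ncol = 3) +
      outer((seq_len(n_beads) - 1) * spacing, axis)
    rows[[i]] <- data.frame(
      lipid_id = i, species = species,
      chain_role = c("none", rep("fatty", n_beads - 1)),
      bead_name = c("HEAD", paste0("F", seq_len(n_beads - 1))),
      mass = 14, is_head = c(TRUE, rep(FALSE, n_beads - 1)))
  }
  df <- do.call(rbind, rows)
  df <- cbind(particle_index = seq_len(nrow(df)) - 1L, df)
  list(topology = sc_topology(df),
       frame = sc_frame(do.call(rbind, co), c(10, 10, 10)))
}

# Independent brute-force kNN oracle (explicit per-pair minimum image).
bf_knn <- function(tails, box, k = 6, k_chol = 7) {
  n <- nrow(tails)
  cls <- if ("tail_class" %in% names(tails)) tails$tail_class else
    tails$tail_type
  lapply(seq_len(n), function(i) {
    d <- vapply(seq_len(n), function(j) {
      dx <- abs(tails$x[i] - tails$x[j]); dx <- min(dx, box[1] - dx)
      dy <- abs(tails$y[i] - tails$y[j]); dy <- min(dy, box[2] - dy)
      dz <- tails$z[i] - tails$z[j]
      sqrt(dx^2 + dy^2 + dz^2)
    }, numeric(1))
    d[i] <- Inf
    kk <- if (cls[i] == "CHOL") k_chol else k
    order(d, seq_len(n))[seq_len(kk)]
  })
}

# Two-domain point clouds mirroring the study's domain-composition table
# (thin sphingosine/CHOL-rich vs thick acyl/FFA-rich).
domain_cloud <- function(n = 400, seed = 1, th = c(5.16, 5.78), sd_th = 0.08,
                         comp_small = c(0.28, 0.36, 0.09, 0.26),
                         comp_large = c(0.34, 0.27, 0.04, 0.34)) {
  set.seed(seed)
  half <- n %/% 2
  lab <- rep(c("smaller", "larger"), c(half, n - half))
  thickness <- c(rnorm(half, th[1], sd_th), rnorm(n - half, th[2], sd_th))
  comp <- rbind(matrix(comp_small, half, 4, byrow = TRUE),
                matrix(comp_large, n - half, 4, byrow = TRUE))
  comp <- comp + matrix(rnorm(n * 4, 0, 0.01), n, 4)
  comp <- comp / rowSums(comp)
  df <- data.frame(thickness = thickness, CER_acyl = comp[, 1],
                   CER_sph = comp[, 2], CHOL = comp[, 3], FFA = comp[, 4])
  attr(df, "labels") <- lab
  df
}

# Table-2-style generator construction shared by domain tests
domain_system <- function(n_lipids = 600, seed = 11) {
  dom <- list(
    list(type = "half_plane", from = 0, to = 0.5, thickness_nm = 5.16,
         enrich = c(CHOL = 2.5, CER_sph = 2.5, CER_acyl = 0.4)),
    list(type = "half_plane", from = 0.5, to = 1, thickness_nm = 5.78,
         enrich = c(FFA = 2, CER_acyl = 2.5, CER_sph = 0.4)))
  make_multilayer(synthetic_spec(n_lipids = n_lipids, domain_spec = dom,
                                 seed = seed))
}
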
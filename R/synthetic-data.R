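# Synthetic multilayer configurations with known ground truth. The
# generator emulates the study systems: three-bilayer (six-leaflet) stacks
# of CER NS / CHOL / FFA at prescribed molar ratios, ~0.2 nm^2 per chain,
# ~35% of CERs extended, flanking water slabs, optional lateral domains of
# distinct thickness/composition, and a tunable orientational disorder.

#' Specification for a synthetic multilayer system
#'
#' @param n_lipids total lipid count (default 2000, as in the emulated
#'   self-assembled systems).
#' @param molar_ratio CER:CHOL:FFA molar ratio, default `c(1, 0.5, 1)`.
#' @param n_leaflets even leaflet count, default 6 (three bilayers).
#' @param area_per_chain in-plane area per chain in nm^2 (default 0.20).
#' @param fraction_extended fraction of interface-eligible CERs generated in
#'   the extended conformation (default 0.35).
#' @param domain_spec list of lateral regions, each a list with `type`
#'   ("half_plane" or "disc"), geometry in box fractions (`from`/`to` along
#'   x for half planes; `center`, `radius_frac` for discs), `thickness_nm`
#'   for the central bilayer inside the region, and optional `enrich`, a
#'   named vector of species sampling multipliers (names CER_NS, CHOL, FFA).
#' @param orientation_kappa concentration of the tail-direction distribution
#'   about the bilayer normal (von Mises-Fisher); larger is straighter.
#' @param water_per_lipid water molecules per lipid (default 40).
#' @param bilayer_thickness base head-to-head bilayer thickness in nm.
#' @param gap head-plane separation between adjacent bilayers in nm.
#' @param resolution `"cg"` (0.47 nm bead rods) or `"atomistic"`
#'   (zigzag carbon chains, 0.127 nm rise per carbon).
#' @param head_jitter,xy_jitter placement noise (nm).
#' @param seed integer; fully determines the output.
#' @return list of class `sc_spec`.
#' @export
synthetic_spec <- function(n_lipids = 2000, molar_ratio = c(1, 0.5, 1),
                           n_leaflets = 6, area_per_chain = 0.20,
                           fraction_extended = 0.35, domain_spec = list(),
                           orientation_kappa = 100, water_per_lipid = 40,
                           bilayer_thickness = 5.4, gap = 0.8,
                           resolution = c("cg", "atomistic"),
                           head_jitter = 0.02, xy_jitter = 0.03, seed = 1) {
  resolution <- match.arg(resolution)
  if (length(molar_ratio) != 3 || any(molar_ratio < 0) || sum(molar_ratio) <= 0)
    stop("molar_ratio must be three non-negative values (CER, CHOL, FFA)")
  if (n_leaflets %% 2 != 0 || n_leaflets < 2) stop("n_leaflets must be even")
  if (fraction_extended < 0 || fraction_extended > 1)
    stop("fraction_extended must be in [0, 1]")
  if (orientation_kappa < 0) stop("orientation_kappa must be >= 0")
  structure(as.list(environment()), class = "sc_spec")
}

#' @export
print.sc_spec <- function(x, ...) {
  cat(sprintf(paste0("<sc_spec> %d lipids, ratio %s, %d leaflets, %s, ",
                     "%.0f%% extended, kappa = %g, seed = %d\n"),
              x$n_lipids, paste(x$molar_ratio, collapse = ":"), x$n_leaflets,
              x$resolution, 100 * x$fraction_extended, x$orientation_kappa,
              x$seed))
  invisible(x)
}

# --- orientation model -----------------------------------------------------

#' Expected nematic order for a von Mises-Fisher tilt distribution
#'
#' Closed form for directions drawn with concentration `kappa` about the
#' bilayer normal: `E[cos^2 theta] = 1 - 2 coth(kappa)/kappa + 2/kappa^2`,
#' and `S2 = (3 E[cos^2 theta] - 1)/2`. Used by the generator to target a
#' desired order parameter.
#'
#' @param kappa concentration (>= 0); 0 is isotropic.
#' @return expected S2 in [0, 1].
#' @export
kappa_to_s2 <- function(kappa) {
  vapply(kappa, function(k) {
    if (k < 1e-8) return(0)
    coth <- if (k > 20) 1 else 1 / tanh(k)
    ec2 <- 1 - 2 * coth / k + 2 / k^2
    (3 * ec2 - 1) / 2
  }, numeric(1))
}

#' @rdname kappa_to_s2
#' @param s2 target order parameter in (0, 1).
#' @export
s2_to_kappa <- function(s2) {
  vapply(s2, function(s) {
    if (s <= 0) return(0)
    if (s >= 1) stop("S2 = 1 requires infinite concentration")
    stats::uniroot(function(k) kappa_to_s2(k) - s, c(1e-3, 1e6),
                   tol = 1e-10)$root
  }, numeric(1))
}

# unit vectors concentrated about +z (von Mises-Fisher on the sphere)
sample_vmf_z <- function(n, kappa) {
  if (kappa < 1e-8) {
    w <- stats::runif(n, -1, 1)
  } else {
    u <- stats::runif(n)
    w <- 1 + log(u * (1 - exp(-2 * kappa)) + exp(-2 * kappa)) / kappa
  }
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - w^2))
  cbind(r * cos(phi), r * sin(phi), abs(w))
}

# --- bead architectures ----------------------------------------------------

chain_beads <- function(species, role, resolution) {
  if (resolution == "cg") {
    n <- switch(paste(species, role),
                "CER_NS acyl" = 6L, "CER_NS sphingosine" = 4L,
                "FFA fatty" = 6L, "CHOL sterol" = 4L)
    list(n = n, spacing = 0.47, zig = 0, mass = 72)
  } else {
    n <- switch(paste(species, role),
                "CER_NS acyl" = 24L, "CER_NS sphingosine" = 18L,
                "FFA fatty" = 24L, "CHOL sterol" = 8L)
    list(n = n, spacing = 0.127, zig = 0.0427, mass = 14)
  }
}

head_beads_of <- function(species) {
  switch(species, CER_NS = CER_HEAD_BEADS, FFA = "HEAD", CHOL = "CHEAD")
}

# --- lateral regions -------------------------------------------------------

region_of_xy <- function(x, y, Lx, Ly, domain_spec) {
  out <- integer(length(x))
  if (!length(domain_spec)) return(out)
  for (r in seq_along(domain_spec)) {
    reg <- domain_spec[[r]]
    inside <- if (reg$type == "half_plane") {
      fx <- x / Lx
      fx >= reg$from & fx < reg$to
    } else if (reg$type == "disc") {
      d <- pbc_xy_distance(cbind(x, y),
                           cbind(rep(reg$center[1] * Lx, length(x)),
                                 rep(reg$center[2] * Ly, length(x))),
                           c(Lx, Ly))
      d <= reg$radius_frac * min(Lx, Ly)
    } else stop("unknown region type: ", reg$type)
    out[out == 0 & inside] <- r
  }
  out
}

region_thickness <- function(region, spec) {
  t <- rep(spec$bilayer_thickness, length(region))
  for (r in seq_along(spec$domain_spec)) {
    th <- spec$domain_spec[[r]]$thickness_nm
    if (!is.null(th)) t[region == r] <- th
  }
  t
}

# enrichment lookup: exact key first (species, or tail-type keys CER_acyl /
# CER_sph for extended CER placement), falling back to the CER_NS species
# multiplier for CER tail-type keys
region_enrich <- function(region, key, spec) {
  w <- rep(1, length(region))
  for (r in seq_along(spec$domain_spec)) {
    e <- spec$domain_spec[[r]]$enrich
    if (is.null(e)) next
    val <- if (key %in% names(e)) e[[key]]
      else if (key %in% c("CER_acyl", "CER_sph") && "CER_NS" %in% names(e))
        e[["CER_NS"]]
      else NA_real_
    if (!is.na(val)) w[region == r] <- val
  }
  w
}

# largest-remainder rounding of n into parts proportional to ratio
apportion <- function(n, ratio) {
  raw <- n * ratio / sum(ratio)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1L
  }
  as.integer(base)
}

# --- the multilayer generator ---------------------------------------------

#' Generate a synthetic multilayer membrane with ground truth
#'
#' Chains are placed on a jittered triangular lattice per leaflet, with
#' bead rods (or zigzag carbon chains) pointing into the membrane along a
#' direction drawn from a z-concentrated von Mises-Fisher distribution.
#' Head beads sit at the leaflet head planes; the central-bilayer head
#' planes are shifted symmetrically about the central midplane to realize
#' per-region thickness, and species placement is region-weighted to
#' realize composition enrichment. CER conformers are drawn to match
#' `fraction_extended` exactly (after rounding) among CERs at internal
#' interfaces: an extended CER keeps its acyl chain in its home leaflet and
#' sends its sphingosine chain into the adjacent leaflet across the
#' interface. Water slabs flank the outer leaflets. Output is fully
#' determined by `spec$seed`.
#'
#' @param spec an [synthetic_spec()].
#' @return an `sc_system` with one frame; attribute `ground_truth` holds
#'   the per-lipid conformer labels, leaflet assignments, head-plane z
#'   positions, per-region thickness, water bookkeeping and the spec.
#' @export
make_multilayer <- function(spec) {
  stopifnot(inherits(spec, "sc_spec"))
  set.seed(spec$seed)
  K <- spec$n_leaflets
  counts <- apportion(spec$n_lipids, spec$molar_ratio)
  names(counts) <- c("CER_NS", "CHOL", "FFA")
  if (any(spec$molar_ratio > 0 & counts == 0))
    stop("composition not representable: a species present in the ratio ",
         "rounds to zero lipids")

  # deterministic lipid list (ids by species block) so that topology is
  # invariant across seeds of the same spec
  lip_species <- rep(names(counts), counts)
  n_lip <- length(lip_species)
  lip_id <- seq_len(n_lip)

  # round-robin leaflet allotment per species
  leaflet_home <- integer(n_lip)
  for (sp in names(counts)) {
    ii <- which(lip_species == sp)
    leaflet_home[ii] <- rep_len(seq_len(K), length(ii))
  }

  # conformers: exact-count sampling among interface-eligible CERs
  conformer <- rep("not_applicable", n_lip)
  cer <- which(lip_species == "CER_NS")
  conformer[cer] <- "hairpin"
  # stratified per home leaflet so that the central bilayer keeps a
  # balanced acyl/sphingosine tail census
  eligible <- cer[leaflet_home[cer] > 1 & leaflet_home[cer] < K]
  ext <- integer(0)
  for (l in unique(leaflet_home[eligible])) {
    el <- eligible[leaflet_home[eligible] == l]
    n_ext <- round(spec$fraction_extended * length(el))
    if (n_ext > 0) ext <- c(ext, sample(el, n_ext))
  }
  conformer[ext] <- "extended"
  partner_leaflet <- function(l) ifelse(l %% 2 == 0, l + 1L, l - 1L)

  # chains per leaflet -> box size
  chains_in <- integer(K)
  for (i in seq_len(n_lip)) {
    l <- leaflet_home[i]
    sp <- lip_species[i]
    if (sp == "CER_NS") {
      if (conformer[i] == "extended") {
        chains_in[l] <- chains_in[l] + 1L
        lp <- partner_leaflet(l)
        chains_in[lp] <- chains_in[lp] + 1L
      } else chains_in[l] <- chains_in[l] + 2L
    } else chains_in[l] <- chains_in[l] + 1L
  }
  n_max <- max(chains_in)
  L <- sqrt(spec$area_per_chain * n_max)
  box_xy <- c(L, L)

  # triangular-ish lattice exactly tiling the box, one per leaflet
  nx <- ceiling(sqrt(n_max))
  ny <- ceiling(n_max / nx)
  ax <- L / nx; ay <- L / ny
  gx <- as.vector(outer(seq_len(nx) - 1, (seq_len(ny) - 1) %% 2 * 0.5, "+")) * ax
  gy <- rep((seq_len(ny) - 0.5) * ay, each = nx)

  # z layout: head planes bottom-up, fixed gap between bilayers
  hw <- max(0.8, water_slab_height(spec, L * L))
  plane_base <- numeric(K)
  zz <- hw
  for (b in seq_len(K / 2)) {
    plane_base[2 * b - 1] <- zz
    plane_base[2 * b] <- zz + spec$bilayer_thickness
    zz <- zz + spec$bilayer_thickness + spec$gap
  }
  Lz <- plane_base[K] + hw
  central_pair <- assign_central_pair(K)
  zc <- mean(plane_base[central_pair])   # central-bilayer midplane

  head_plane_z <- function(l, x, y) {
    if (!(l %in% central_pair) || !length(spec$domain_spec))
      return(plane_base[l])
    reg <- region_of_xy(x, y, L, L, spec$domain_spec)
    t <- region_thickness(reg, spec)
    if (l == central_pair[1]) zc - t / 2 else zc + t / 2
  }

  # per-leaflet site bookkeeping
  sites <- lapply(seq_len(K), function(l)
    list(x = gx + stats::rnorm(length(gx), 0, spec$xy_jitter),
         y = gy + stats::rnorm(length(gy), 0, spec$xy_jitter),
         free = rep(TRUE, length(gx))))
  site_region <- lapply(sites, function(s) region_of_xy(s$x, s$y, L, L,
                                                        spec$domain_spec))
  take_site <- function(l, species) {
    s <- sites[[l]]
    free <- which(s$free)
    if (!length(free)) stop("leaflet ", l, " lattice exhausted")
    w <- region_enrich(site_region[[l]][free], species, spec)
    if (all(w <= 0)) w <- rep(1, length(free))
    i <- if (length(free) == 1) free else sample(free, 1, prob = w)
    sites[[l]]$free[i] <<- FALSE
    i
  }
  take_nearest_free <- function(l, x0, y0) {
    s <- sites[[l]]
    free <- which(s$free)
    if (!length(free)) stop("leaflet ", l, " lattice exhausted")
    d <- pbc_xy_distance(cbind(s$x[free], s$y[free]),
                         cbind(rep(x0, length(free)), rep(y0, length(free))),
                         box_xy)
    i <- free[which.min(d)]
    sites[[l]]$free[i] <<- FALSE
    i
  }

  # accumulate bead records
  acc <- new.env(parent = emptyenv())
  acc$co <- vector("list", 4 * n_lip); acc$meta <- vector("list", 4 * n_lip)
  acc$k <- 0L
  emit <- function(co, lipid, species, role, names, mass, is_head) {
    acc$k <- acc$k + 1L
    acc$co[[acc$k]] <- co
    acc$meta[[acc$k]] <- list(lipid = lipid, species = species, role = role,
                              names = names, mass = mass, is_head = is_head)
  }

  place_chain <- function(lipid, species, role, l, x0, y0) {
    cb <- chain_beads(species, role, spec$resolution)
    sigma <- if (l %% 2 == 1) 1 else -1     # odd leaflets: tails point up
    u <- sample_vmf_z(1, spec$orientation_kappa)
    d <- c(u[1], u[2], sigma * u[3])
    zh <- head_plane_z(l, x0, y0)
    anchor <- c(x0, y0, zh + sigma * 0.05)
    along <- 0.15 + cb$spacing * (seq_len(cb$n) - 1)
    co <- matrix(rep(anchor, each = cb$n), ncol = 3) +
      outer(along, d)
    if (cb$zig > 0) {
      ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      p <- c(d[2] * ref[3] - d[3] * ref[2],
             d[3] * ref[1] - d[1] * ref[3],
             d[1] * ref[2] - d[2] * ref[1])
      p <- p / sqrt(sum(p^2))
      co <- co + outer(cb$zig * (-1)^(seq_len(cb$n)), p)
    }
    prefix <- switch(role, acyl = "A", sphingosine = "S", sterol = "C",
                     fatty = "F")
    emit(co, lipid, species, rep(role, cb$n), paste0(prefix, seq_len(cb$n)),
         rep(cb$mass, cb$n), rep(FALSE, cb$n))
  }

  place_heads <- function(lipid, species, l, x0, y0) {
    hb <- head_beads_of(species)
    n <- length(hb)
    zh <- head_plane_z(l, x0, y0)
    co <- cbind(x0 + stats::rnorm(n, 0, 0.02),
                y0 + stats::rnorm(n, 0, 0.02),
                zh + stats::rnorm(n, 0, spec$head_jitter))
    m <- if (spec$resolution == "cg") 72 else 30
    emit(co, lipid, species, rep("none", n), hb, rep(m, n), rep(TRUE, n))
  }

  order_place <- c(which(lip_species == "CER_NS" & conformer == "hairpin"),
                   which(lip_species == "CER_NS" & conformer == "extended"),
                   which(lip_species != "CER_NS"))
  partner_of <- integer(n_lip)
  for (i in order_place) {
    sp <- lip_species[i]
    l <- leaflet_home[i]
    if (sp == "CER_NS") {
      # extended CERs contribute only one chain to the central bilayer:
      # the acyl chain when the home leaflet is central, else the
      # sphingosine chain, so lateral enrichment keys on that chain type
      site_key <- if (conformer[i] == "extended") {
        if (l %in% central_pair) "CER_acyl" else "CER_sph"
      } else sp
      i1 <- take_site(l, site_key)
      x0 <- sites[[l]]$x[i1]; y0 <- sites[[l]]$y[i1]
      place_heads(i, sp, l, x0, y0)
      place_chain(i, sp, "acyl", l, x0, y0)
      if (conformer[i] == "extended") {
        lp <- partner_leaflet(l)
        partner_of[i] <- lp
        i2 <- take_nearest_free(lp, x0, y0)
        place_chain(i, sp, "sphingosine", lp, sites[[lp]]$x[i2],
                    sites[[lp]]$y[i2])
      } else {
        i2 <- take_nearest_free(l, x0, y0)
        place_chain(i, sp, "sphingosine", l, sites[[l]]$x[i2],
                    sites[[l]]$y[i2])
      }
    } else {
      i1 <- take_site(l, sp)
      x0 <- sites[[l]]$x[i1]; y0 <- sites[[l]]$y[i1]
      place_heads(i, sp, l, x0, y0)
      place_chain(i, sp, if (sp == "CHOL") "sterol" else "fatty", l, x0, y0)
    }
  }

  # water slabs at bulk density
  n_water_mol <- round(spec$water_per_lipid * n_lip)
  per_bead <- if (spec$resolution == "cg") 4 else 1
  n_wb <- ceiling(n_water_mol / per_bead)
  wmass <- if (spec$resolution == "cg") 72 else 18
  if (n_wb > 0) {
    nlo <- ceiling(n_wb / 2); nhi <- n_wb - nlo
    wlo <- cbind(stats::runif(nlo, 0, L), stats::runif(nlo, 0, L),
                 stats::runif(nlo, 0, plane_base[1]))
    whi <- cbind(stats::runif(nhi, 0, L), stats::runif(nhi, 0, L),
                 stats::runif(nhi, plane_base[K], Lz))
    wco <- rbind(wlo, whi)
    emit(wco, 0L, "WATER", rep("none", n_wb), rep("W", n_wb),
         rep(wmass, n_wb), rep(FALSE, n_wb))
  }

  # emit order depends on conformer sampling; reorder blocks by lipid id
  # so the topology is identical across seeds of one spec (water last)
  meta <- acc$meta[seq_len(acc$k)]
  blk_lip <- vapply(meta, function(m) if (m$lipid == 0L) Inf else
    as.numeric(m$lipid), numeric(1))
  ord <- order(blk_lip)
  meta <- meta[ord]
  co <- do.call(rbind, acc$co[seq_len(acc$k)][ord])
  nb <- vapply(meta, function(m) length(m$mass), integer(1))
  lipid_ids <- unlist(mapply(function(m, n) rep(m$lipid, n), meta, nb,
                             SIMPLIFY = FALSE))
  # water beads get their own lipid ids after the lipids
  wsel <- lipid_ids == 0L
  if (any(wsel)) lipid_ids[wsel] <- n_lip + seq_len(sum(wsel))
  topo <- sc_topology(data.frame(
    particle_index = seq_len(nrow(co)) - 1L,
    lipid_id = lipid_ids,
    species = unlist(mapply(function(m, n) rep(m$species, n), meta, nb,
                            SIMPLIFY = FALSE)),
    chain_role = unlist(lapply(meta, function(m) m$role)),
    bead_name = unlist(lapply(meta, function(m) m$names)),
    mass = unlist(lapply(meta, function(m) m$mass)),
    is_head = unlist(lapply(meta, function(m) m$is_head)),
    stringsAsFactors = FALSE))
  frame <- sc_frame(co, c(L, L, Lz))
  truth <- list(
    seed = spec$seed, spec = unclass(spec),
    lipids = data.frame(lipid_id = lip_id, species = lip_species,
                        leaflet = leaflet_home, conformer = conformer,
                        partner_leaflet = ifelse(partner_of > 0, partner_of,
                                                 NA_integer_),
                        stringsAsFactors = FALSE),
    head_plane_z = plane_base, central_pair = central_pair,
    central_midplane = zc,
    central_thickness_base = spec$bilayer_thickness,
    region_thickness = if (length(spec$domain_spec))
      vapply(spec$domain_spec, function(r)
        if (is.null(r$thickness_nm)) spec$bilayer_thickness else r$thickness_nm,
        numeric(1)) else numeric(0),
    n_water_molecules = n_water_mol,
    membrane_span = plane_base[K] - plane_base[1])
  structure(list(topology = topo, frames = list(frame)),
            class = "sc_system", ground_truth = truth)
}

assign_central_pair <- function(K) {
  nb <- K / 2
  ctr <- ceiling((nb + 1) / 2)
  c(2L * ctr - 1L, 2L * ctr)
}

water_slab_height <- function(spec, area) {
  n_mol <- spec$water_per_lipid * spec$n_lipids
  if (spec$resolution == "cg") {
    (n_mol / 4) / 2 / (8.35 * area)   # 4 waters per bead, 8.35 beads/nm^3
  } else {
    n_mol / 2 / (33.4 * area)
  }
}

#' Ground truth of a generated system
#'
#' @param system a system produced by [make_multilayer()].
#' @return the ground-truth list recorded at generation time.
#' @export
ground_truth <- function(system) attr(system, "ground_truth")

#' Write generator ground truth as JSON
#'
#' @param system a generated `sc_system`.
#' @param path output JSON path.
#' @export
write_ground_truth <- function(system, path) {
  gt <- ground_truth(system)
  if (is.null(gt)) stop("system carries no ground truth")
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Water-per-outer-leaflet-lipid bookkeeping
#'
#' Hydrating water contacts only the two outer leaflets of a stack, so the
#' hydration level per solvated lipid is the water count divided by the
#' lipids of the two outer leaflets (`n_lipids * 2 / n_leaflets`).
#'
#' @param n_waters water molecule count.
#' @param n_lipids total lipid count.
#' @param n_leaflets leaflet count (default 6).
#' @return water molecules per outer-leaflet lipid.
#' @export
waters_per_outer_lipid <- function(n_waters, n_lipids, n_leaflets = 6) {
  if (n_lipids <= 0 || n_leaflets <= 0) stop("counts must be positive")
  n_waters / (n_lipids * 2 / n_leaflets)
}

#' Perfectly mixed synthetic central bilayer
#'
#' Lattice tail positions with types assigned i.i.d. from the composition
#' and CER conformer labels assigned independently of position — the null
#' configuration in which every normalized neighbor-pair count has
#' expectation 1.
#'
#' @param n_tails number of tails (warning below 50).
#' @param composition fractions over the four tail types, named
#'   `CER_acyl`, `CER_sph`, `CHOL`, `FFA`; must sum to 1. Default is the
#'   tail composition of a 1:0.5:1 CER/CHOL/FFA mixture (2:2:1:2)/7.
#' @param fraction_extended probability a CER tail is labelled extended.
#' @param area_per_chain lattice area per tail, nm^2.
#' @param seed RNG seed.
#' @return data.frame with `tail_class`, `tail_type`, `conformer`, `x`,
#'   `y`, `z` and attribute `box` (Lx, Ly, Lz).
#' @export
make_mixed_central_bilayer <- function(n_tails,
                                       composition = c(CER_acyl = 2, CER_sph = 2,
                                                       CHOL = 1, FFA = 2) / 7,
                                       fraction_extended = 0.35,
                                       area_per_chain = 0.20, seed = 1) {
  if (abs(sum(composition) - 1) > 1e-8) stop("composition must sum to 1")
  if (!all(names(composition) %in% TAIL_TYPES))
    stop("composition names must be among: ", paste(TAIL_TYPES, collapse = ", "))
  if (n_tails < 50) warning("fewer than 50 tails: statistics unreliable")
  set.seed(seed)
  nx <- ceiling(sqrt(n_tails)); ny <- ceiling(n_tails / nx)
  L <- sqrt(area_per_chain * n_tails)
  ax <- L / nx; ay <- L / ny
  x <- (as.vector(outer(seq_len(nx) - 1, (seq_len(ny) - 1) %% 2 * 0.5, "+")) * ax)
  y <- rep((seq_len(ny) - 0.5) * ay, each = nx)
  keep <- sample(length(x), n_tails)
  x <- x[keep] + stats::rnorm(n_tails, 0, 0.02)
  y <- y[keep] + stats::rnorm(n_tails, 0, 0.02)
  ty <- sample(names(composition), n_tails, replace = TRUE, prob = composition)
  conf <- ifelse(ty %in% c("CER_acyl", "CER_sph"),
                 ifelse(stats::runif(n_tails) < fraction_extended,
                        "extended", "hairpin"),
                 "not_applicable")
  df <- data.frame(tail_type = ty, conformer = conf,
                   tail_class = tail_class_of(ty, conf),
                   x = x, y = y, z = 0, stringsAsFactors = FALSE)
  attr(df, "box") <- c(L, L, 1)
  df
}

#' Piecewise disorder model for a temperature sweep
#'
#' Maps temperature to the generator's orientation concentration and an
#' in-plane area scale, linear in T with a hinge at `breakpoint` — the
#' construction used to test two-regime recovery with a known transition.
#'
#' @param breakpoint transition temperature, degC (default 65).
#' @param s2_low order parameter at `t_ref` (default 0.91, the well-ordered
#'   regime level).
#' @param slope_low,slope_high dS2/dT below and above the breakpoint.
#' @param area_slope_low,area_slope_high d(area scale)/dT per regime.
#' @param t_ref reference temperature, degC.
#' @return function(T) returning list(kappa, area_scale, s2_target).
#' @export
make_disorder_model <- function(breakpoint = 65, s2_low = 0.91,
                                slope_low = -5e-4, slope_high = -1.2e-2,
                                area_slope_low = 5e-4, area_slope_high = 4e-3,
                                t_ref = 30) {
  force(breakpoint)
  function(T) {
    s2b <- s2_low + slope_low * (breakpoint - t_ref)
    s2 <- ifelse(T < breakpoint, s2_low + slope_low * (T - t_ref),
                 s2b + slope_high * (T - breakpoint))
    s2 <- pmin(0.99, pmax(0.2, s2))
    ab <- 1 + area_slope_low * (breakpoint - t_ref)
    a <- ifelse(T < breakpoint, 1 + area_slope_low * (T - t_ref),
                ab + area_slope_high * (T - breakpoint))
    list(kappa = s2_to_kappa(s2), area_scale = a, s2_target = s2)
  }
}

#' Generate a temperature sweep of synthetic configurations
#'
#' One configuration per temperature, sharing a topology, with orientation
#' disorder and lateral area following `disorder_model`. Frames are tagged
#' with their temperature.
#'
#' @param spec an [synthetic_spec()] (defines composition, size, seed).
#' @param t_grid ascending temperatures in degC.
#' @param disorder_model function from [make_disorder_model()] (default:
#'   a 65 degC hinge).
#' @return an `sc_system` whose frames are tagged by temperature;
#'   attribute `sweep_truth` records the model's targets per frame.
#' @export
make_temperature_sweep <- function(spec, t_grid,
                                   disorder_model = make_disorder_model()) {
  if (is.unsorted(t_grid, strictly = TRUE)) stop("t_grid must be ascending")
  frames <- vector("list", length(t_grid))
  topo <- NULL
  truth <- data.frame(T = t_grid, kappa = NA_real_, area_scale = NA_real_,
                      s2_target = NA_real_)
  for (i in seq_along(t_grid)) {
    m <- disorder_model(t_grid[i])
    sp <- spec
    sp$orientation_kappa <- m$kappa
    sp$area_per_chain <- spec$area_per_chain * m$area_scale
    sp$seed <- spec$seed + 7919L * i
    sys <- make_multilayer(sp)
    fr <- sys$frames[[1]]
    fr$tag <- t_grid[i]
    frames[[i]] <- fr
    if (is.null(topo)) topo <- sys$topology
    truth$kappa[i] <- m$kappa
    truth$area_scale[i] <- m$area_scale
    truth$s2_target[i] <- m$s2_target
  }
  structure(list(topology = topo, frames = frames), class = "sc_system",
            sweep_truth = truth)
}

#' Attach pseudo-hydrogens to chain carbons
#'
#' For every interior carbon of every lipid chain, two unit C-H vectors are
#' constructed perpendicular to the local chain axis (the vector between
#' the flanking carbons) from the angle bisector and the normal of the
#' C-C-C plane, with C-H length 0.109 nm. Collinear chain sections fall
#' back to a deterministic perpendicular pair.
#'
#' @param frame an `sc_frame`.
#' @param topology an `sc_topology`.
#' @return data.frame: `lipid_id`, `chain_role`, `tail_type`,
#'   `carbon_index` (2..n-1), `h` (1 or 2), unit vector `hx`, `hy`, `hz`,
#'   and hydrogen position `px`, `py`, `pz` (nm).
#' @export
attach_pseudo_hydrogens <- function(frame, topology) {
  topo <- topology
  tails <- topo$species != "WATER" & !topo$is_head
  sub <- topo[tails, ]
  co <- frame$coords[tails, , drop = FALSE]
  key <- paste(sub$lipid_id, sub$chain_role)
  idx <- split(seq_len(nrow(sub)), key)
  half <- 54.75 * pi / 180     # half H-C-H angle
  out <- vector("list", length(idx))
  for (q in seq_along(idx)) {
    ii <- idx[[q]]
    n <- length(ii)
    if (n < 3)
      stop("chain with fewer than 3 carbons: lipid ", sub$lipid_id[ii[1]],
           " ", sub$chain_role[ii[1]])
    P <- co[ii, , drop = FALSE]
    rows <- vector("list", n - 2)
    for (c_i in 2:(n - 1)) {
      a <- P[c_i - 1, ] - P[c_i, ]; a <- a / sqrt(sum(a^2))
      b <- P[c_i + 1, ] - P[c_i, ]; b <- b / sqrt(sum(b^2))
      bis <- a + b
      if (sqrt(sum(bis^2)) > 1e-8) {
        u1 <- -bis / sqrt(sum(bis^2))
        u2 <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
                a[1] * b[2] - a[2] * b[1])
        u2 <- u2 / sqrt(sum(u2^2))
      } else {
        ax <- P[c_i + 1, ] - P[c_i - 1, ]; ax <- ax / sqrt(sum(ax^2))
        ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        u1 <- c(ax[2] * ref[3] - ax[3] * ref[2],
                ax[3] * ref[1] - ax[1] * ref[3],
                ax[1] * ref[2] - ax[2] * ref[1])
        u1 <- u1 / sqrt(sum(u1^2))
        u2 <- c(ax[2] * u1[3] - ax[3] * u1[2], ax[3] * u1[1] - ax[1] * u1[3],
                ax[1] * u1[2] - ax[2] * u1[1])
      }
      h1 <- cos(half) * u1 + sin(half) * u2
      h2 <- cos(half) * u1 - sin(half) * u2
      rows[[c_i - 1]] <- cbind(carbon = c_i, h = 1:2,
                               rbind(h1, h2),
                               rbind(P[c_i, ] + 0.109 * h1,
                                     P[c_i, ] + 0.109 * h2))
    }
    m <- do.call(rbind, rows)
    out[[q]] <- data.frame(
      lipid_id = sub$lipid_id[ii[1]], chain_role = sub$chain_role[ii[1]],
      tail_type = switch(sub$chain_role[ii[1]], acyl = "CER_acyl",
                         sphingosine = "CER_sph", sterol = "CHOL",
                         fatty = "FFA"),
      carbon_index = m[, 1], h = m[, 2],
      hx = m[, 3], hy = m[, 4], hz = m[, 5],
      px = m[, 6], py = m[, 7], pz = m[, 8],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Synthesize a 1D scattering profile
#'
#' Sum of Pearson VII peaks plus a flat background and optional Gaussian
#' noise on an ascending q grid; deterministic given `seed`.
#'
#' @param peaks data.frame with columns `q0` (nm^-1), `amplitude`,
#'   `width` (half width at half maximum, nm^-1), `shape` (Pearson VII
#'   exponent m > 0.5).
#' @param q ascending q grid, nm^-1.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param background flat background level.
#' @param seed RNG seed (only used when `noise_sd > 0`).
#' @return data.frame `q`, `intensity` (clamped at 0).
#' @export
make_saxd_profile <- function(peaks, q, noise_sd = 0, background = 0,
                              seed = 1) {
  if (any(q <= 0) || is.unsorted(q, strictly = TRUE))
    stop("q grid must be positive and strictly ascending")
  I <- rep(background, length(q))
  for (i in seq_len(nrow(peaks)))
    I <- I + pearson_vii(q, peaks$q0[i], peaks$amplitude[i],
                         peaks$width[i], peaks$shape[i])
  if (noise_sd > 0) {
    set.seed(seed)
    I <- I + stats::rnorm(length(q), 0, noise_sd)
  }
  data.frame(q = q, intensity = pmax(I, 0))
}
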
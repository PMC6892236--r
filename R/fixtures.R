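## Deterministic synthetic-data generators: toy parent pairs with designed
## secondary structure, ideal-geometry coordinate builders, kinetics /
## thermal / synergy datasets with planted parameters, and multi-frame
## trajectories with planted hydrogen bonds. Every generator returns its
## planted truth alongside the data; the same seed always yields the same
## output (Mersenne-Twister, locally scoped so callers' RNG state is left
## untouched).

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

#' Generate a synthetic homologous parent pair
#'
#' Parent A is drawn uniformly over the 20 amino acids under `seed`; parent B
#' is derived by substituting `divergence_pct` percent of positions (the
#' shared secondary-structure layout is an annotation and is never broken by
#' substitutions) and, optionally, inserting or deleting single residues only
#' inside interior coil regions of the layout. This emulates a pair of
#' homologous enzyme catalytic domains of moderate identity.
#'
#' @param seed Integer seed.
#' @param length Length of parent A; must equal `nchar(ss_layout)`.
#' @param ss_layout Shared secondary-structure template over `{H,E,C}`.
#' @param divergence_pct Percent of positions substituted in B (0-100).
#' @param indels Number of single-residue insertions/deletions applied to B
#'   (coil regions only; generation error if no interior coil run of >= 3).
#' @return List of class `parent_pair_fixture`: `a`, `b` ([seq_record()]),
#'   `ss_a`, `ss_b`, `truth` (seed and parameters).
#' @export
make_parent_pair <- function(seed, length, ss_layout = strrep("C", length),
                             divergence_pct = 0, indels = 0L) {
  stopifnot(nchar(ss_layout) == length, divergence_pct >= 0,
            divergence_pct <= 100)
  if (grepl("[^HEC]", ss_layout))
    stop("ss_layout may contain only H, E, C", call. = FALSE)
  .with_seed(seed, {
    aa <- .AA_ALPHABET
    a_chars <- sample(aa, length, replace = TRUE)
    b_chars <- a_chars
    nsub <- round(divergence_pct / 100 * length)
    if (nsub > 0) {
      pos <- sample.int(length, nsub)
      for (p in pos) b_chars[p] <- sample(setdiff(aa, b_chars[p]), 1)
    }
    ss_b_chars <- strsplit(ss_layout, "")[[1]]
    if (indels > 0L) {
      for (k in seq_len(indels)) {
        runs <- .interior_coil_runs(paste(ss_b_chars, collapse = ""))
        runs <- runs[runs$len >= 3L, , drop = FALSE]
        if (!nrow(runs))
          stop("no interior coil run of >= 3 residues for indel placement",
               call. = FALSE)
        run <- runs[sample.int(nrow(runs), 1L), ]
        at <- run$start + sample.int(run$len, 1L) - 1L
        if (stats::runif(1) < 0.5 && run$len > 3L) {      # deletion
          b_chars <- b_chars[-at]
          ss_b_chars <- ss_b_chars[-at]
        } else {                                           # insertion
          b_chars <- append(b_chars, sample(aa, 1), after = at)
          ss_b_chars <- append(ss_b_chars, "C", after = at)
        }
      }
    }
    list(a = seq_record("parentA", paste(a_chars, collapse = "")),
         b = seq_record("parentB", paste(b_chars, collapse = "")),
         ss_a = ss_layout, ss_b = paste(ss_b_chars, collapse = ""),
         truth = list(seed = seed, length = length,
                      divergence_pct = divergence_pct, indels = indels)) |>
      structure(class = "parent_pair_fixture")
  })
}

.interior_coil_runs <- function(ss) {
  n <- nchar(ss)
  r <- rle(strsplit(ss, "")[[1]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == "C"
  ## clip away the first/last residue of the chain so indels stay interior
  starts <- pmax(starts[keep], 2L)
  ends <- pmin(ends[keep], n - 1L)
  ok <- ends >= starts
  data.frame(start = starts[ok], len = ends[ok] - starts[ok] + 1L)
}

#' Secondary-structure layout that admits a known fragment count
#'
#' Convenience builder: `n_internal + 2` fragments are feasible under the
#' default demarcation parameters when `n_internal + 1` interior coil gaps
#' separate structured blocks of suitable size. Returns a layout string of
#' terminal coils, `n_internal + 1` structured blocks, and coil gaps.
#'
#' @param n_fragments Total fragment count the layout should admit (>= 3).
#' @param block Length of each structured (helix) block (default 9).
#' @param gap Length of each interior coil gap (default 4).
#' @param cap Length of the terminal coils (default 5).
#' @return The layout string.
#' @export
ss_layout_for_fragments <- function(n_fragments, block = 9L, gap = 4L,
                                    cap = 5L) {
  stopifnot(n_fragments >= 3L)
  nblocks <- n_fragments - 1L
  paste0(strrep("C", cap),
         paste(rep(paste0(strrep("H", block), strrep("C", gap)),
                   nblocks - 1L), collapse = ""),
         strrep("H", block), strrep("C", cap))
}

## ---- ideal-geometry coordinate builders ------------------------------------

## extend a chain by one atom given the three previous atoms and internal
## coordinates (NeRF construction)
.place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180; dih <- -dihedral * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an ideal polypeptide backbone from dihedral angles
#'
#' Constructs N/CA/C backbone coordinates for `n` residues with the given
#' phi/psi (omega fixed at 180 degrees) and standard bond geometry
#' (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom; angles N-CA-C 111.2,
#' CA-C-N 116.2, C-N-CA 121.7 degrees).
#'
#' @param n Number of residues (>= 2).
#' @param phi,psi Backbone dihedrals in degrees (recycled). Ideal alpha-helix:
#'   (-57, -47); ideal beta-strand: (-120, 120).
#' @param chain Chain id.
#' @param res_name Residue name for all residues.
#' @return A [structure_model()] with N, CA, C atoms per residue.
#' @export
make_backbone <- function(n, phi = -57, psi = -47, chain = "A",
                          res_name = "ALA") {
  stopifnot(n >= 2L)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329
  a_ncac <- 111.2; a_cacn <- 116.2; a_cnca <- 121.7
  coords <- list()
  coords[["N1"]] <- c(0, 0, 0)
  coords[["CA1"]] <- c(b_nca, 0, 0)
  ang <- a_ncac * pi / 180
  coords[["C1"]] <- coords[["CA1"]] +
    c(-b_cac * cos(ang), b_cac * sin(ang), 0)
  for (i in 2:n) {
    coords[[paste0("N", i)]] <- .place_atom(
      coords[[paste0("N", i - 1)]], coords[[paste0("CA", i - 1)]],
      coords[[paste0("C", i - 1)]], b_cn, a_cacn, psi[i - 1])
    coords[[paste0("CA", i)]] <- .place_atom(
      coords[[paste0("CA", i - 1)]], coords[[paste0("C", i - 1)]],
      coords[[paste0("N", i)]], b_nca, a_cnca, 180)   # omega
    coords[[paste0("C", i)]] <- .place_atom(
      coords[[paste0("C", i - 1)]], coords[[paste0("N", i)]],
      coords[[paste0("CA", i)]], b_cac, a_ncac, phi[i])
  }
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(chain = chain, res_seq = i, res_name = res_name,
               atom_name = c("N", "CA", "C"), element = c("N", "C", "C"),
               x = c(coords[[paste0("N", i)]][1], coords[[paste0("CA", i)]][1],
                     coords[[paste0("C", i)]][1]),
               y = c(coords[[paste0("N", i)]][2], coords[[paste0("CA", i)]][2],
                     coords[[paste0("C", i)]][2]),
               z = c(coords[[paste0("N", i)]][3], coords[[paste0("CA", i)]][3],
                     coords[[paste0("C", i)]][3]))
  }))
  structure_model(atoms, model_index = 1L, source = "make_backbone")
}

#' Rigid-body transform of a structure model
#'
#' Rotation (by Euler-like angles about x, y, z in degrees) followed by
#' translation. Used to test invariance of geometric statistics.
#'
#' @param model A [structure_model()].
#' @param angles Length-3 rotation angles (degrees).
#' @param shift Length-3 translation (Angstrom).
#' @return The transformed `structure_model`.
#' @export
transform_model <- function(model, angles = c(0, 0, 0), shift = c(0, 0, 0)) {
  th <- angles * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0),
              c(0, 0, 1))
  R <- rz %*% ry %*% rx
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  out <- model
  out$atoms$x <- xyz[, 1] + shift[1]
  out$atoms$y <- xyz[, 2] + shift[2]
  out$atoms$z <- xyz[, 3] + shift[3]
  out
}

## ---- assay-data generators -------------------------------------------------

#' Synthetic Michaelis-Menten kinetics data
#'
#' `v_i = Vmax S_i / (Km + S_i) * (1 + e_i)`, `e_i ~ N(0, noise_cv)`:
#' multiplicative Gaussian noise, matching how assay replicate scatter scales
#' with signal. The default substrate grid spans 0.5-10 mg/mL, the range used
#' for polymeric xylan kinetics.
#'
#' @param seed Integer seed.
#' @param km,vmax Planted parameters (mg/mL, umol/min/mg).
#' @param s_grid Substrate concentrations (mg/mL).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 = exact curve).
#' @return List: `table` (an `assay_table` of kind kinetics), `truth`.
#' @export
make_kinetics <- function(seed, km, vmax, s_grid = c(0.5, 1, 2, 4, 6, 8, 10),
                          noise_cv = 0) {
  stopifnot(km > 0, vmax > 0, all(s_grid > 0))
  .with_seed(seed, {
    v <- vmax * s_grid / (km + s_grid)
    if (noise_cv > 0) v <- v * (1 + stats::rnorm(length(s_grid), 0, noise_cv))
    v <- pmax(v, .Machine$double.eps)
    list(table = assay_table(data.frame(substrate_mg_per_mL = s_grid, rate = v),
                             kind = "kinetics"),
         truth = list(seed = seed, km = km, vmax = vmax, noise_cv = noise_cv))
  })
}

#' Synthetic thermal-inactivation (T50) data
#'
#' Falling logistic on the percent scale with additive Gaussian noise
#' truncated to \[0, 110\]%.
#'
#' @param seed Integer seed.
#' @param t50 Planted midpoint (degrees C).
#' @param s Planted slope (degrees C, default 2).
#' @param temps Temperature grid (default 30-80 C, every 2.5 C).
#' @param noise_sd Additive noise SD in percentage points.
#' @return List: `table` (`assay_table`, kind thermal_T50), `truth`.
#' @export
make_t50 <- function(seed, t50, s = 2, temps = seq(30, 80, by = 2.5),
                     noise_sd = 0) {
  stopifnot(s > 0)
  .with_seed(seed, {
    r <- 100 / (1 + exp((temps - t50) / s))
    if (noise_sd > 0)
      r <- pmin(pmax(r + stats::rnorm(length(temps), 0, noise_sd), 0), 110)
    list(table = assay_table(data.frame(temperature_C = temps, residual_pct = r),
                             kind = "thermal_T50"),
         truth = list(seed = seed, t50 = t50, s = s, noise_sd = noise_sd))
  })
}

#' Synthetic first-order decay (half-life) data
#'
#' @param seed Integer seed.
#' @param t_half Planted half-life (h).
#' @param r0 Initial residual activity (%).
#' @param times Time grid (h).
#' @param noise_sd Additive noise SD in percentage points (truncated > 0).
#' @return List: `table` (`assay_table`, kind thermal_decay), `truth` (with
#'   the implied rate `k = ln 2 / t_half`).
#' @export
make_decay <- function(seed, t_half, r0 = 100, times = seq(0, 4, by = 0.5),
                       noise_sd = 0) {
  stopifnot(t_half > 0)
  .with_seed(seed, {
    k <- log(2) / t_half
    r <- r0 * exp(-k * times)
    if (noise_sd > 0)
      r <- pmax(r + stats::rnorm(length(times), 0, noise_sd), 1e-6)
    list(table = assay_table(data.frame(time_h = times, residual_pct = r),
                             kind = "thermal_decay"),
         truth = list(seed = seed, t_half = t_half, k = k, r0 = r0,
                      noise_sd = noise_sd))
  })
}

#' Synthetic mixed-enzyme hydrolysis time course
#'
#' Parameterized directly by a target degree-of-synergy profile plus the
#' single-enzyme arm trajectories, so [degree_of_synergy()] has a closed-form
#' oracle: `Y_both(t) = DS(t) * (Y_cel(t) + Y_xyl(t))` exactly (noise, when
#' requested, is applied multiplicatively to all arms with the same factor at
#' each time point, preserving DS).
#'
#' @param seed Integer seed.
#' @param times Time grid (h), default 1..15.
#' @param y_cel,y_xyl Arm trajectories: functions of time or numeric vectors
#'   (umol/mL). Defaults rise saturatingly to 3.2 and 0.45 umol/mL at 15 h.
#' @param ds_profile Target DS as a function of time or a numeric vector.
#' @param y_control Control-arm value(s) (default 0.05 umol/mL).
#' @param noise_cv CV of the shared multiplicative noise factor.
#' @return List: `table` (`assay_table`, kind synergy), `truth` (the DS
#'   profile values).
#' @export
make_synergy <- function(seed, times = 1:15,
                         y_cel = function(t) 3.2 * (1 - exp(-t / 5)) /
                           (1 - exp(-3)),
                         y_xyl = function(t) 0.45 * (1 - exp(-t / 5)) /
                           (1 - exp(-3)),
                         ds_profile = function(t) 0.85 + 0.3 * t / 15,
                         y_control = 0.05, noise_cv = 0) {
  .with_seed(seed, {
    ev <- function(f) if (is.function(f)) f(times) else rep_len(f, length(times))
    yc <- ev(y_cel); yx <- ev(y_xyl); ds <- ev(ds_profile)
    yb <- ds * (yc + yx)
    ctl <- ev(y_control)
    if (noise_cv > 0) {
      fac <- 1 + stats::rnorm(length(times), 0, noise_cv)
      yc <- yc * fac; yx <- yx * fac; yb <- yb * fac; ctl <- ctl * fac
    }
    list(table = assay_table(data.frame(time_h = times, both = yb,
                                        cellulase_only = yc,
                                        xylanase_only = yx, control = ctl),
                             kind = "synergy"),
         truth = list(seed = seed, ds = ds, noise_cv = noise_cv))
  })
}

## ---- trajectory generator ---------------------------------------------------

#' Synthetic multi-frame trajectory with planted hydrogen bonds
#'
#' Builds `n_frames` frames over a fixed atom roster of donor/acceptor pairs
#' plus decoy atoms. Each pair is a serine-like hydroxyl donor (OG with its
#' hydrogen HG) and a glutamate-like carboxylate acceptor (OE2) in separate
#' residues. On frames scheduled for a pair, the acceptor sits 2.9 Angstrom
#' from the donor on the O-H axis (D-H-A angle 180 degrees); on other frames
#' it is displaced to 6 Angstrom. Decoy atoms are placed on a lattice at
#' least 8 Angstrom from everything, so they are never bonded.
#'
#' @param seed Integer seed (placement jitter of decoys).
#' @param n_frames Number of frames.
#' @param n_pairs Number of donor/acceptor pairs (named `P1`, `P2`, ...).
#' @param bond_schedule Named list: pair name -> integer frame indices on
#'   which that pair is bonded. Indices must be within `1..n_frames`.
#' @param n_decoys Number of decoy (alanine backbone O) atoms.
#' @return List of class `trajectory_fixture`: `frames` (list of
#'   [structure_model()]), `pairs` (data.frame `pair`, `donor`, `acceptor`
#'   atom ids), `truth` (the schedule and implied occupancies in percent).
#' @export
make_trajectory <- function(seed, n_frames = 20L, n_pairs = 1L,
                            bond_schedule = list(P1 = seq_len(n_frames)),
                            n_decoys = 10L) {
  stopifnot(n_frames >= 1L, n_pairs >= 1L)
  if (!all(names(bond_schedule) %in% paste0("P", seq_len(n_pairs))))
    stop("bond_schedule names must be P1..P", n_pairs, call. = FALSE)
  if (length(unlist(bond_schedule)) &&
      any(unlist(bond_schedule) < 1 | unlist(bond_schedule) > n_frames))
    stop("bond_schedule frame indices out of range", call. = FALSE)
  .with_seed(seed, {
    jitter <- stats::runif(n_decoys * 3, -0.5, 0.5)
    frames <- lapply(seq_len(n_frames), function(f) {
      rows <- list()
      for (p in seq_len(n_pairs)) {
        base <- c(20 * p, 0, 0)
        don_res <- 2L * p - 1L; acc_res <- 2L * p
        bonded <- f %in% (bond_schedule[[paste0("P", p)]] %||% integer(0))
        d_acc <- if (bonded) 2.9 else 6.0
        rows[[length(rows) + 1L]] <- data.frame(
          chain = "A", res_seq = don_res, res_name = "SER",
          atom_name = c("OG", "HG"), element = c("O", "H"),
          x = base[1] + c(0, 1.0), y = base[2], z = base[3])
        rows[[length(rows) + 1L]] <- data.frame(
          chain = "A", res_seq = acc_res, res_name = "GLU",
          atom_name = "OE2", element = "O",
          x = base[1] + d_acc, y = base[2], z = base[3])
      }
      if (n_decoys > 0L) {
        idx <- seq_len(n_decoys)
        rows[[length(rows) + 1L]] <- data.frame(
          chain = "B", res_seq = 100L + idx, res_name = "ALA",
          atom_name = "O", element = "O",
          x = 8 * idx + jitter[idx],
          y = 50 + jitter[n_decoys + idx],
          z = 50 + jitter[2 * n_decoys + idx])
      }
      structure_model(do.call(rbind, rows), model_index = f,
                      source = "make_trajectory")
    })
    pair_ids <- data.frame(
      pair = paste0("P", seq_len(n_pairs)),
      donor = sprintf("S_%d@OG", 2L * seq_len(n_pairs) - 1L),
      acceptor = sprintf("E_%d@OE2", 2L * seq_len(n_pairs)))
    occ <- vapply(pair_ids$pair, function(p)
      100 * length(bond_schedule[[p]] %||% integer(0)) / n_frames, 0)
    structure(list(frames = frames, pairs = pair_ids,
                   truth = list(seed = seed, schedule = bond_schedule,
                                occupancy_pct = stats::setNames(occ, pair_ids$pair))),
              class = "trajectory_fixture")
  })
}

#' Write a fixture's data and planted truth to disk
#'
#' Writes the fixture's primary data in its standard external format (CSV for
#' assay fixtures, FASTA + secondary-structure text for parent pairs,
#' multi-model PDB for trajectories) plus an adjacent `truth.json` recording
#' the planted parameters.
#'
#' @param x A fixture object returned by one of the `make_*` generators.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_fixture <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(f) files <<- c(files, f)
  if (inherits(x, "parent_pair_fixture")) {
    f <- file.path(dir, "parents.fasta")
    write_fasta(list(x$a, x$b), f); put(f)
    f <- file.path(dir, "parents.ss")
    writeLines(c(x$ss_a, x$ss_b), f); put(f)
    truth <- x$truth
  } else if (inherits(x, "trajectory_fixture")) {
    f <- file.path(dir, "trajectory.pdb")
    write_pdb(x$frames, f); put(f)
    truth <- x$truth
  } else if (!is.null(x$table)) {
    f <- file.path(dir, paste0(attr(x$table, "kind"), ".csv"))
    write_assay_table(x$table, f); put(f)
    truth <- x$truth
  } else stop("unknown fixture type", call. = FALSE)
  tf <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, tf, auto_unbox = TRUE, digits = NA)
  put(tf)
  invisible(files)
}
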
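## Geometric hydrogen-bond detection and frame-fraction occupancy over
## multi-model coordinate frames. Post-processing only: no dynamics engine,
## no energies -- a donor-hydrogen-acceptor triple is a bond iff the
## donor-acceptor distance and the D-H-A angle satisfy the criteria.

.ONE_LETTER <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                 GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                 LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                 SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

## default per-residue donor/acceptor catalogue: backbone N donates (except
## proline), backbone O accepts, plus the polar side-chain atoms
.default_donors <- function() {
  side <- list(ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
               HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
               TRP = "NE1", TYR = "OH")
  list(backbone = "N", exclude_backbone = "PRO", side = side)
}

.default_acceptors <- function() {
  side <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1",
               GLN = "OE1", SER = "OG", THR = "OG1", TYR = "OH",
               HIS = c("ND1", "NE2"))
  list(backbone = "O", side = side)
}

#' Hydrogen-bond geometric criteria
#'
#' @param max_da_dist Maximum donor-acceptor heavy-atom distance in Angstrom
#'   (default 3.5, the common geometric convention).
#' @param min_dha_angle Minimum donor-hydrogen-acceptor angle in degrees
#'   (default 120).
#' @param donors,acceptors Per-residue atom catalogues; defaults cover
#'   backbone N (non-proline) / backbone O plus the polar side chains of the
#'   20 standard residues.
#' @return A list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_da_dist = 3.5, min_dha_angle = 120,
                           donors = .default_donors(),
                           acceptors = .default_acceptors()) {
  stopifnot(max_da_dist > 0, min_dha_angle >= 0, min_dha_angle <= 180)
  structure(list(max_da_dist = max_da_dist, min_dha_angle = min_dha_angle,
                 donors = donors, acceptors = acceptors),
            class = "hbond_criteria")
}

.atom_id <- function(res_name, res_seq, atom_name) {
  one <- .ONE_LETTER[res_name]
  one[is.na(one)] <- "X"
  sprintf("%s_%d@%s", one, res_seq, atom_name)
}

.is_donor <- function(atoms, donors) {
  if (!nrow(atoms)) return(logical(0))
  bb <- atoms$atom_name == donors$backbone &
    !(atoms$res_name %in% donors$exclude_backbone)
  sc <- vapply(seq_len(nrow(atoms)), function(i)
    atoms$atom_name[i] %in% (donors$side[[atoms$res_name[i]]] %||% character(0)),
    TRUE)
  bb | sc
}

.is_acceptor <- function(atoms, acceptors) {
  if (!nrow(atoms)) return(logical(0))
  bb <- atoms$atom_name == acceptors$backbone
  sc <- vapply(seq_len(nrow(atoms)), function(i)
    atoms$atom_name[i] %in% (acceptors$side[[atoms$res_name[i]]] %||% character(0)),
    TRUE)
  bb | sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect hydrogen bonds in one coordinate frame
#'
#' A (donor, hydrogen, acceptor) triple is reported iff the donor and
#' acceptor are catalogued, belong to different residues, their heavy-atom
#' distance is at most `max_da_dist`, and the D-H-A angle is at least
#' `min_dha_angle`. Hydrogens are attached to their donor geometrically
#' (within 1.25 Angstrom). If the frame carries no hydrogens at all (typical
#' of crystallographic input), detection falls back to the distance criterion
#' alone and the result is flagged with attribute `distance_only = TRUE`.
#'
#' @param frame A [structure_model()].
#' @param criteria [hbond_criteria()].
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor` (atom ids
#'   of the form `"E_153@OE2"`), plus `da_dist` and `dha_angle` (`NA` in
#'   distance-only mode).
#' @export
detect_hbonds <- function(frame, criteria = hbond_criteria()) {
  stopifnot(inherits(frame, "structure_model"))
  a <- frame$atoms
  if (!nrow(a)) stop("empty frame", call. = FALSE)
  hyd <- a[a$element == "H" | grepl("^H", a$atom_name), ]
  heavy <- a[!(a$element == "H" | grepl("^H", a$atom_name)), ]
  don <- heavy[.is_donor(heavy, criteria$donors), ]
  acc <- heavy[.is_acceptor(heavy, criteria$acceptors), ]
  distance_only <- nrow(hyd) == 0L
  out <- list()
  if (nrow(don) && nrow(acc)) {
    dx <- outer(don$x, acc$x, "-")
    dy <- outer(don$y, acc$y, "-")
    dz <- outer(don$z, acc$z, "-")
    dist <- sqrt(dx^2 + dy^2 + dz^2)
    same_res <- outer(paste(don$chain, don$res_seq), paste(acc$chain, acc$res_seq),
                      "==")
    hits <- which(dist <= criteria$max_da_dist & !same_res, arr.ind = TRUE)
    if (nrow(hits)) {
      for (r in seq_len(nrow(hits))) {
        di <- hits[r, 1]; ai <- hits[r, 2]
        d_id <- .atom_id(don$res_name[di], don$res_seq[di], don$atom_name[di])
        a_id <- .atom_id(acc$res_name[ai], acc$res_seq[ai], acc$atom_name[ai])
        if (distance_only) {
          out[[length(out) + 1L]] <- data.frame(
            donor = d_id, hydrogen = NA_character_, acceptor = a_id,
            da_dist = dist[di, ai], dha_angle = NA_real_)
          next
        }
        ## hydrogens bonded to this donor
        hd <- sqrt((hyd$x - don$x[di])^2 + (hyd$y - don$y[di])^2 +
                     (hyd$z - don$z[di])^2)
        att <- which(hd <= 1.25 & hyd$res_seq == don$res_seq[di] &
                       hyd$chain == don$chain[di])
        for (hi in att) {
          v1 <- c(don$x[di] - hyd$x[hi], don$y[di] - hyd$y[hi],
                  don$z[di] - hyd$z[hi])
          v2 <- c(acc$x[ai] - hyd$x[hi], acc$y[ai] - hyd$y[hi],
                  acc$z[ai] - hyd$z[hi])
          cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
          if (ang >= criteria$min_dha_angle)
            out[[length(out) + 1L]] <- data.frame(
              donor = d_id,
              hydrogen = .atom_id(hyd$res_name[hi], hyd$res_seq[hi],
                                  hyd$atom_name[hi]),
              acceptor = a_id, da_dist = dist[di, ai], dha_angle = ang)
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(donor = character(0), hydrogen = character(0),
                         acceptor = character(0), da_dist = numeric(0),
                         dha_angle = numeric(0))
  res <- unique(res)
  rownames(res) <- NULL
  attr(res, "distance_only") <- distance_only
  res
}

#' Hydrogen-bond occupancy over coordinate frames
#'
#' Occupancy of a donor-acceptor pair is the percentage of window frames in
#' which the pair is hydrogen-bonded (via any hydrogen) under the criteria.
#'
#' @param frames List of [structure_model()] frames with identical atom
#'   rosters.
#' @param pairs `"all"` (every pair ever bonded in the window) or a
#'   data.frame with columns `donor`, `acceptor` (atom ids) to be reported
#'   explicitly (including 0% rows).
#' @param criteria [hbond_criteria()].
#' @param window Integer vector of frame indices to analyze (default: all
#'   frames), or a string `"last:P%"` selecting the final P percent of
#'   frames.
#' @return data.frame with columns `donor`, `acceptor`, `occupancy_pct`,
#'   `n_frames`, sorted by descending occupancy.
#' @export
occupancy <- function(frames, pairs = "all", criteria = hbond_criteria(),
                      window = NULL) {
  if (inherits(frames, "structure_model")) frames <- list(frames)
  stopifnot(length(frames) >= 1L)
  rosters <- lapply(frames, function(f)
    paste(f$atoms$chain, f$atoms$res_seq, f$atoms$atom_name))
  if (!all(vapply(rosters, identical, TRUE, y = rosters[[1]])))
    stop("atom rosters differ across frames", call. = FALSE)
  if (is.null(window)) window <- seq_along(frames)
  if (is.character(window)) window <- parse_window(window, length(frames))
  if (!length(window) || any(window < 1L | window > length(frames)))
    stop("window indices out of range", call. = FALSE)
  bonded <- lapply(frames[window], function(f) {
    hb <- detect_hbonds(f, criteria)
    unique(paste(hb$donor, hb$acceptor, sep = "|"))
  })
  nwin <- length(window)
  counts <- table(unlist(bonded))
  if (identical(pairs, "all")) {
    keys <- names(counts) %||% character(0)
    occ <- as.numeric(counts) / nwin * 100
  } else {
    keys <- paste(pairs$donor, pairs$acceptor, sep = "|")
    occ <- as.numeric(counts[keys]) / nwin * 100
    occ[is.na(occ)] <- 0
  }
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- data.frame(donor = vapply(parts, `[`, "", 1),
                    acceptor = vapply(parts, `[`, "", 2),
                    occupancy_pct = occ, n_frames = rep(nwin, length(keys)))
  out <- out[order(-out$occupancy_pct, out$donor, out$acceptor), ]
  rownames(out) <- NULL
  out
}

#' Parse a frame-window specification
#'
#' `"last:25%"` selects the final 25% of `n` frames (at least one);
#' `"first:25%"` the initial 25%; `"all"` everything.
#'
#' @param spec Window string.
#' @param n Total number of frames.
#' @return Integer vector of frame indices.
#' @export
parse_window <- function(spec, n) {
  if (identical(spec, "all")) return(seq_len(n))
  m <- regexec("^(last|first):([0-9.]+)%$", spec)[[1]]
  if (m[1] == -1) stop("bad window spec: ", spec, call. = FALSE)
  parts <- regmatches(spec, regexec("^(last|first):([0-9.]+)%$", spec))[[1]]
  k <- max(1L, round(n * as.numeric(parts[3]) / 100))
  if (parts[2] == "last") seq.int(n - k + 1L, n) else seq_len(k)
}
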
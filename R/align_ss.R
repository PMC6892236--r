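## Pairwise global alignment of the two parents plus 3-state secondary
## structure, producing the annotated object fragment demarcation consumes.

.load_submat <- function(name) {
  ok <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
          "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")
  if (!name %in% ok) stop("unknown substitution matrix: ", name, call. = FALSE)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

.check_ss <- function(ss, seq, label) {
  if (is.null(ss)) return(strrep("C", nchar(seq)))
  stopifnot(is.character(ss), length(ss) == 1L)
  if (nchar(ss) != nchar(seq))
    stop(sprintf("secondary-structure string for %s has length %d, sequence has %d",
                 label, nchar(ss), nchar(seq)), call. = FALSE)
  if (grepl("[^HEC]", ss))
    stop("secondary-structure strings may contain only H, E, C", call. = FALSE)
  ss
}

#' Globally align two parent enzymes
#'
#' Needleman-Wunsch global alignment with affine gap penalties (gap run of
#' length L costs `gap_open + gap_extend * L`), via
#' [Biostrings::pairwiseAlignment()]. Percent identity is computed over
#' aligned (non-gap) residue pairs only.
#'
#' Secondary-structure strings annotate each parent with 3-state labels
#' (H/E/C). They are carried through to demarcation, which only cuts where
#' both parents are coil; supplying curated strings (e.g. from a DSSP run) is
#' the preferred route for exact reproduction of a published demarcation.
#' When omitted they default to all-coil, which places no structural
#' constraint on cut sites.
#'
#' @param a,b [seq_record()] objects (amino acid).
#' @param ss_a,ss_b Secondary-structure strings over `{H,E,C}`, same length
#'   as the corresponding sequence, or `NULL` (all-coil).
#' @param gap_open,gap_extend Affine gap penalties (defaults 10, 0.5).
#' @param matrix Substitution matrix name bundled with \pkg{Biostrings}
#'   (default `"BLOSUM62"`).
#' @return An object of class `aligned_parents`: fields `parent_a`,
#'   `parent_b`, `ss_a`, `ss_b`, `columns` (data.frame `a_pos`, `b_pos`, `NA`
#'   at gaps), `identity_pct`, `score`, `params`.
#' @examples
#' a <- seq_record("A", "ACDEFGHIK")
#' b <- seq_record("B", "ACDEGHIK")
#' ap <- align_parents(a, b)
#' ap$identity_pct
#' @export
align_parents <- function(a, b, ss_a = NULL, ss_b = NULL,
                          gap_open = 10, gap_extend = 0.5,
                          matrix = "BLOSUM62") {
  stopifnot(inherits(a, "seq_record"), inherits(b, "seq_record"))
  if (a$type != "AA" || b$type != "AA")
    stop("align_parents expects amino-acid records", call. = FALSE)
  ss_a <- .check_ss(ss_a, a$seq, a$id)
  ss_b <- .check_ss(ss_b, b$seq, b$id)
  submat <- .load_submat(matrix)
  pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(a$seq),
                                      Biostrings::AAString(b$seq),
                                      type = "global",
                                      substitutionMatrix = submat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  al_a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  al_b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  a_pos <- ifelse(al_a == "-", NA_integer_, cumsum(al_a != "-"))
  b_pos <- ifelse(al_b == "-", NA_integer_, cumsum(al_b != "-"))
  columns <- data.frame(a_pos = as.integer(a_pos), b_pos = as.integer(b_pos))
  paired <- !is.na(columns$a_pos) & !is.na(columns$b_pos)
  ident <- sum(al_a[paired] == al_b[paired]) / sum(paired) * 100
  structure(list(parent_a = a, parent_b = b, ss_a = ss_a, ss_b = ss_b,
                 columns = columns, identity_pct = ident,
                 score = Biostrings::score(pa),
                 params = list(gap_open = gap_open, gap_extend = gap_extend,
                               matrix = matrix)),
            class = "aligned_parents")
}

#' Recompute an alignment score from its column list
#'
#' Self-consistency check: sums substitution scores over aligned pairs and
#' subtracts `gap_open + gap_extend * L` per maximal gap run. Equals
#' `ap$score` for any alignment emitted by [align_parents()].
#'
#' @param ap An `aligned_parents` object.
#' @return Numeric score.
#' @export
alignment_score <- function(ap) {
  stopifnot(inherits(ap, "aligned_parents"))
  submat <- .load_submat(ap$params$matrix)
  ca <- strsplit(ap$parent_a$seq, "")[[1]]
  cb <- strsplit(ap$parent_b$seq, "")[[1]]
  cols <- ap$columns
  s <- 0
  for (i in seq_len(nrow(cols))) {
    if (!is.na(cols$a_pos[i]) && !is.na(cols$b_pos[i]))
      s <- s + submat[ca[cols$a_pos[i]], cb[cols$b_pos[i]]]
  }
  for (gapcol in list(is.na(cols$a_pos), is.na(cols$b_pos))) {
    r <- rle(gapcol)
    runs <- r$lengths[r$values]
    s <- s - sum(ap$params$gap_open + ap$params$gap_extend * runs)
  }
  s
}

#' @export
print.aligned_parents <- function(x, ...) {
  cat(sprintf("<aligned_parents> %s (%d aa) vs %s (%d aa)\n",
              x$parent_a$id, nchar(x$parent_a$seq),
              x$parent_b$id, nchar(x$parent_b$seq)))
  cat(sprintf("  %d columns, identity %.1f%%, score %.1f (%s, open %g, extend %g)\n",
              nrow(x$columns), x$identity_pct, x$score,
              x$params$matrix, x$params$gap_open, x$params$gap_extend))
  invisible(x)
}

## ---- secondary structure from backbone geometry ----------------------------

## dihedral angle (degrees) for points p1-p2-p3-p4, each a length-3 vector
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

.in_helix_phi <- function(phi) !is.na(phi) & phi >= -100 & phi <= -30
.in_helix_psi <- function(psi) !is.na(psi) & psi >= -80 & psi <= -5
.in_strand_phi <- function(phi) !is.na(phi) & phi >= -180 & phi <= -60
.in_strand_psi <- function(psi) !is.na(psi) &
  ((psi >= 60 & psi <= 180) | (psi >= -180 & psi <= -150))

#' Assign 3-state secondary structure from backbone dihedrals
#'
#' Computes phi/psi for every residue of `chain` with complete backbone
#' (N, CA, C) and classifies each residue as helical (phi in \[-100, -30\],
#' psi in \[-80, -5\]), extended (phi in \[-180, -60\], psi in \[60, 180\] or
#' \[-180, -150\]) or coil. Terminal residues, which have only one of the two
#' dihedrals, are classified on the available angle. Runs of at least 4
#' consecutive helical residues become `H`, runs of at least 3 extended
#' residues become `E`; everything else (including residues with missing
#' backbone atoms) is `C`. This is a deliberately simple, testable dihedral
#' proxy, not a hydrogen-bond-based assignment; curated strings can always be
#' supplied to [align_parents()] instead.
#'
#' @param model A [structure_model()].
#' @param chain Chain identifier.
#' @return Single string over `{H,E,C}`, one character per residue of the
#'   chain (in `res_seq` order).
#' @export
assign_secondary_structure <- function(model, chain = "A") {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms[model$atoms$chain == chain, ]
  if (!nrow(at)) stop("chain '", chain, "' not found", call. = FALSE)
  resids <- sort(unique(at$res_seq))
  n <- length(resids)
  if (n < 3L) stop("chain must have at least 3 residues", call. = FALSE)
  getxyz <- function(res, name) {
    row <- at[at$res_seq == res & at$atom_name == name, ]
    if (nrow(row) != 1L) return(NULL)
    c(row$x, row$y, row$z)
  }
  bb <- lapply(resids, function(r)
    list(N = getxyz(r, "N"), CA = getxyz(r, "CA"), C = getxyz(r, "C")))
  complete <- vapply(bb, function(b) !any(vapply(b, is.null, TRUE)), TRUE)
  consecutive <- c(TRUE, diff(resids) == 1L)
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!complete[i]) next
    if (i > 1 && complete[i - 1] && consecutive[i])
      phi[i] <- .dihedral(bb[[i - 1]]$C, bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C)
    if (i < n && complete[i + 1] && consecutive[i + 1])
      psi[i] <- .dihedral(bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C, bb[[i + 1]]$N)
  }
  any_angle <- !is.na(phi) | !is.na(psi)
  helical <- complete & any_angle &
    (is.na(phi) | .in_helix_phi(phi)) & (is.na(psi) | .in_helix_psi(psi))
  extended <- complete & any_angle & !helical &
    (is.na(phi) | .in_strand_phi(phi)) & (is.na(psi) | .in_strand_psi(psi))
  states <- rep("C", n)
  states[.keep_runs(helical, 4L)] <- "H"
  states[.keep_runs(extended, 3L)] <- "E"
  paste(states, collapse = "")
}

## logical index of positions inside TRUE-runs of length >= min_len
.keep_runs <- function(flag, min_len) {
  r <- rle(flag)
  keep <- r$values & r$lengths >= min_len
  rep(keep, r$lengths)
}
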
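## Fragment demarcation: partition the aligned parents into swap-compatible
## fragments under two hard constraints -- (1) every boundary falls in coil on
## both parents and never interrupts a helix or strand run, and (2) every
## internal (non-terminal) fragment is at most max_internal_len residues on
## BOTH parents. Which of the eligible coil columns become boundaries is
## decided by a small dynamic program under an explicit objective.

#' Demarcation parameters
#'
#' @param max_internal_len Maximum length (residues) of an internal fragment
#'   on either parent. Default 19, the strict reading of a "shorter than 20
#'   residues" rule.
#' @param min_fragment_len Minimum length of any fragment on either parent
#'   (default 5; a 1-residue "fragment" is a point mutation, not a fragment).
#' @param eligibility_window Number of alignment columns on each side of a
#'   candidate junction that must be aligned (non-gap in both parents).
#'   Default 1.
#' @param objective `"max_internal_count"` (maximize the number of internal
#'   fragments) or `"target_count"` (exactly `target_count` fragments).
#' @param target_count Required fragment count when
#'   `objective = "target_count"`.
#' @return A list of class `demarcation_params`.
#' @export
demarcation_params <- function(max_internal_len = 19L, min_fragment_len = 5L,
                               eligibility_window = 1L,
                               objective = c("max_internal_count", "target_count"),
                               target_count = NULL) {
  objective <- match.arg(objective)
  stopifnot(min_fragment_len >= 1L, min_fragment_len <= max_internal_len,
            eligibility_window >= 0L)
  if (objective == "target_count" &&
      (is.null(target_count) || target_count < 1L))
    stop("objective 'target_count' requires target_count >= 1", call. = FALSE)
  structure(list(max_internal_len = as.integer(max_internal_len),
                 min_fragment_len = as.integer(min_fragment_len),
                 eligibility_window = as.integer(eligibility_window),
                 objective = objective,
                 target_count = if (is.null(target_count)) NULL
                                else as.integer(target_count)),
            class = "demarcation_params")
}

## SS state of each alignment column on one parent (NA at gaps)
.col_ss <- function(pos, ss) {
  st <- strsplit(ss, "")[[1]]
  ifelse(is.na(pos), NA_character_, st[pos])
}

## would cutting after residue `pos` split an H/E run?
.splits_run <- function(pos, ss) {
  st <- strsplit(ss, "")[[1]]
  if (pos < 1L || pos >= length(st)) return(FALSE)
  st[pos] != "C" && st[pos + 1L] == st[pos]
}

#' Enumerate eligible cut sites
#'
#' A cut after alignment column `c` (the junction between columns `c` and
#' `c + 1`) is eligible iff (i) columns `c - w .. c + 1 + w` all exist and are
#' aligned (non-gap in both parents), where `w` is the eligibility window;
#' (ii) the residues at column `c` are coil (`C`) on both parents; and (iii)
#' the cut does not interrupt a helix or strand run on either parent.
#'
#' @param ap An `aligned_parents` object (see [align_parents()]).
#' @param params [demarcation_params()].
#' @return data.frame with columns `column` (alignment column the cut falls
#'   after), `a_pos`, `b_pos` (residue on each parent after which the cut
#'   falls). Possibly zero rows.
#' @export
find_cut_candidates <- function(ap, params = demarcation_params()) {
  stopifnot(inherits(ap, "aligned_parents"))
  cols <- ap$columns
  n <- nrow(cols)
  w <- params$eligibility_window
  aligned <- !is.na(cols$a_pos) & !is.na(cols$b_pos)
  ssa <- .col_ss(cols$a_pos, ap$ss_a)
  ssb <- .col_ss(cols$b_pos, ap$ss_b)
  ok <- logical(n)
  for (c in seq_len(n)) {
    lo <- c - w; hi <- c + 1L + w
    if (lo < 1L || hi > n) next
    if (!all(aligned[lo:hi])) next
    if (!identical(ssa[c], "C") || !identical(ssb[c], "C")) next
    if (.splits_run(cols$a_pos[c], ap$ss_a)) next
    if (.splits_run(cols$b_pos[c], ap$ss_b)) next
    ok[c] <- TRUE
  }
  data.frame(column = which(ok), a_pos = cols$a_pos[ok], b_pos = cols$b_pos[ok])
}

## residue counts of columns (from+1 .. to] on both parents
.seg_len <- function(cols, from, to) {
  idx <- seq.int(from + 1L, to)
  c(a = sum(!is.na(cols$a_pos[idx])), b = sum(!is.na(cols$b_pos[idx])))
}

## DP: best scheme with exactly k cuts from candidate columns `cand`.
## Comparator: smaller sum of squared internal-fragment lengths, then
## lexicographically smaller cut vector (leftmost cuts). Returns integer
## vector of cut columns or NULL if infeasible.
.best_cuts_exact <- function(cols, cand, k, params) {
  ncols <- nrow(cols)
  if (k == 0L) {
    len <- .seg_len(cols, 0L, ncols)
    if (all(len >= params$min_fragment_len)) return(integer(0))
    return(NULL)
  }
  m <- length(cand)
  if (m < k) return(NULL)
  minl <- params$min_fragment_len; maxl <- params$max_internal_len
  ## best[[j]][[q]] = list(cost, cuts) best scheme of q cuts ending with cut j
  best <- vector("list", m)
  first_ok <- vapply(seq_len(m), function(j)
    all(.seg_len(cols, 0L, cand[j]) >= minl), TRUE)
  for (j in seq_len(m)) {
    best[[j]] <- vector("list", k)
    if (first_ok[j]) best[[j]][[1L]] <- list(cost = 0, cuts = cand[j])
    for (i in seq_len(j - 1L)) {
      len <- .seg_len(cols, cand[i], cand[j])
      if (any(len < minl) || any(len > maxl)) next
      add <- sum(len^2)
      for (q in seq_len(k - 1L)) {
        prev <- best[[i]][[q]]
        if (is.null(prev)) next
        candidate <- list(cost = prev$cost + add, cuts = c(prev$cuts, cand[j]))
        cur <- best[[j]][[q + 1L]]
        if (is.null(cur) || .cuts_better(candidate, cur))
          best[[j]][[q + 1L]] <- candidate
      }
    }
  }
  out <- NULL
  for (j in seq_len(m)) {
    fin <- best[[j]][[k]]
    if (is.null(fin)) next
    if (!all(.seg_len(cols, cand[j], ncols) >= minl)) next
    if (is.null(out) || .cuts_better(fin, out)) out <- fin
  }
  if (is.null(out)) NULL else out$cuts
}

.cuts_better <- function(x, y) {
  if (x$cost != y$cost) return(x$cost < y$cost)
  ## lexicographic: leftmost cut vector wins
  d <- x$cuts - y$cuts
  nz <- which(d != 0)
  if (!length(nz)) FALSE else d[nz[1]] < 0
}

#' Partition aligned parents into swap-compatible fragments
#'
#' Selects a subset of the eligible cut sites (see [find_cut_candidates()])
#' by dynamic programming. Under `objective = "max_internal_count"` the
#' number of internal fragments is maximized subject to all scheme
#' invariants; under `"target_count"` a scheme with exactly
#' `params$target_count` fragments is returned if feasible. Ties are broken
#' by most-even internal fragment lengths (minimum sum of squared lengths
#' over both parents), then by leftmost cuts, so output is deterministic.
#'
#' @param ap An `aligned_parents` object.
#' @param params [demarcation_params()].
#' @return Object of class `fragment_scheme`: `fragments` data.frame
#'   (`name`, `a_start`, `a_end`, `b_start`, `b_end`, `terminal`),
#'   `cut_columns`, `params`, and the parent ids.
#' @export
partition_fragments <- function(ap, params = demarcation_params()) {
  stopifnot(inherits(ap, "aligned_parents"))
  cand <- find_cut_candidates(ap, params)$column
  cols <- ap$columns
  if (params$objective == "max_internal_count") {
    kmax <- .max_feasible_cuts(cols, cand, params)
    if (is.na(kmax))
      stop("no feasible fragment scheme: parents shorter than min_fragment_len",
           call. = FALSE)
    cuts <- .best_cuts_exact(cols, cand, kmax, params)
  } else {
    k <- params$target_count - 1L
    cuts <- .best_cuts_exact(cols, cand, k, params)
    if (is.null(cuts)) {
      kmax <- .max_feasible_cuts(cols, cand, params)
      stop(sprintf("target_count %d infeasible; maximum achievable fragment count is %d",
                   params$target_count,
                   if (is.na(kmax)) 0L else kmax + 1L), call. = FALSE)
    }
  }
  .scheme_from_cuts(ap, cuts, params)
}

## largest k with a feasible exact-k scheme (NA if even k = 0 infeasible)
.max_feasible_cuts <- function(cols, cand, params) {
  ncols <- nrow(cols)
  minl <- params$min_fragment_len; maxl <- params$max_internal_len
  m <- length(cand)
  ## f[j] = max cuts in a feasible prefix ending with cut j
  f <- rep(NA_integer_, m)
  for (j in seq_len(m)) {
    if (all(.seg_len(cols, 0L, cand[j]) >= minl)) f[j] <- 1L
    for (i in seq_len(j - 1L)) {
      if (is.na(f[i])) next
      len <- .seg_len(cols, cand[i], cand[j])
      if (any(len < minl) || any(len > maxl)) next
      f[j] <- max(f[j], f[i] + 1L, na.rm = TRUE)
    }
  }
  last_ok <- vapply(seq_len(m), function(j)
    all(.seg_len(cols, cand[j], ncols) >= minl), TRUE)
  k <- suppressWarnings(max(f[last_ok], na.rm = TRUE))
  if (is.finite(k)) return(as.integer(k))
  if (all(.seg_len(cols, 0L, ncols) >= minl)) 0L else NA_integer_
}

.scheme_from_cuts <- function(ap, cuts, params) {
  cols <- ap$columns
  bounds <- c(0L, sort(cuts), nrow(cols))
  nfrag <- length(bounds) - 1L
  frag <- lapply(seq_len(nfrag), function(i) {
    idx <- seq.int(bounds[i] + 1L, bounds[i + 1L])
    ai <- cols$a_pos[idx]; bi <- cols$b_pos[idx]
    data.frame(name = paste0("M", i),
               a_start = min(ai, na.rm = TRUE), a_end = max(ai, na.rm = TRUE),
               b_start = min(bi, na.rm = TRUE), b_end = max(bi, na.rm = TRUE),
               terminal = i == 1L || i == nfrag)
  })
  structure(list(fragments = do.call(rbind, frag),
                 cut_columns = sort(cuts), params = params,
                 parent_a = ap$parent_a$id, parent_b = ap$parent_b$id),
            class = "fragment_scheme")
}

#' @export
print.fragment_scheme <- function(x, ...) {
  cat(sprintf("<fragment_scheme> %d fragments of %s / %s (max internal len %d)\n",
              nrow(x$fragments), x$parent_a, x$parent_b,
              x$params$max_internal_len))
  print(x$fragments, row.names = FALSE)
  invisible(x)
}

#' Validate a fragment scheme against its alignment
#'
#' Checks every scheme invariant: intervals tile each parent exactly (no
#' overlap, no gap), terminal flags on first/last fragments only, internal
#' fragments within `max_internal_len` on both parents, all fragments at
#' least `min_fragment_len`, and no boundary interrupting an H/E run on
#' either parent.
#'
#' @param scheme A `fragment_scheme`.
#' @param ap The `aligned_parents` it was derived from.
#' @return A list of violations (empty iff the scheme is valid); each element
#'   has `type`, `fragment`, `message`.
#' @export
validate_scheme <- function(scheme, ap) {
  stopifnot(inherits(scheme, "fragment_scheme"), inherits(ap, "aligned_parents"))
  fr <- scheme$fragments
  p <- scheme$params
  v <- list()
  add <- function(type, fragment, message)
    v[[length(v) + 1L]] <<- list(type = type, fragment = fragment,
                                 message = message)
  n <- nrow(fr)
  for (side in c("a", "b")) {
    st <- fr[[paste0(side, "_start")]]; en <- fr[[paste0(side, "_end")]]
    plen <- nchar(if (side == "a") ap$parent_a$seq else ap$parent_b$seq)
    if (st[1] != 1L) add("tiling", fr$name[1],
                         sprintf("parent %s does not start at residue 1", side))
    if (en[n] != plen) add("tiling", fr$name[n],
                           sprintf("parent %s does not end at residue %d", side, plen))
    if (n > 1L) for (i in seq_len(n - 1L)) {
      if (st[i + 1L] != en[i] + 1L)
        add("tiling", fr$name[i + 1L],
            sprintf("parent %s intervals not contiguous at %s|%s", side,
                    fr$name[i], fr$name[i + 1L]))
    }
    len <- en - st + 1L
    for (i in seq_len(n)) {
      internal <- !(i == 1L || i == n)
      if (internal && len[i] > p$max_internal_len)
        add("length", fr$name[i],
            sprintf("internal fragment %s has %d residues on parent %s (max %d)",
                    fr$name[i], len[i], side, p$max_internal_len))
      if (len[i] < p$min_fragment_len)
        add("length", fr$name[i],
            sprintf("fragment %s has %d residues on parent %s (min %d)",
                    fr$name[i], len[i], side, p$min_fragment_len))
    }
    ss <- if (side == "a") ap$ss_a else ap$ss_b
    if (n > 1L) for (i in seq_len(n - 1L)) {
      if (.splits_run(en[i], ss))
        add("secondary_structure", fr$name[i],
            sprintf("boundary after %s splits an %s run on parent %s",
                    fr$name[i], substr(ss, en[i], en[i]), side))
    }
  }
  expected_terminal <- seq_len(n) %in% c(1L, n)
  if (!identical(fr$terminal, expected_terminal))
    add("terminal_flags", NA_character_,
        "terminal flags must mark exactly the first and last fragments")
  v
}

#' Write / read a fragment scheme as TSV
#'
#' Columns: `name`, `a_start`, `a_end`, `b_start`, `b_end`, `terminal`.
#'
#' @param scheme A `fragment_scheme`.
#' @param path Output path.
#' @return `path` invisibly (writer); a `fragment_scheme` (reader; `params`
#'   and cut columns are not round-tripped).
#' @export
write_scheme <- function(scheme, path) {
  utils::write.table(scheme$fragments, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_scheme
#' @param parent_a,parent_b Parent ids to record on the read scheme.
#' @export
read_scheme <- function(path, parent_a = "A", parent_b = "B") {
  fr <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  structure(list(fragments = fr, cut_columns = integer(0),
                 params = demarcation_params(),
                 parent_a = parent_a, parent_b = parent_b),
            class = "fragment_scheme")
}
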
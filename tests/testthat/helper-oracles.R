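# Independent oracles used by the tests. These deliberately re-derive results
# by brute force / closed form, never by calling the code paths they check.

# exhaustive global-alignment optimum with affine gaps (gap run of length L
# costs open + ext * L); plain recursion, feasible for sequences up to ~6
oracle_align_score <- function(sa, sb, submat, open = 10, ext = 0.5) {
  ca <- strsplit(sa, "")[[1]]
  cb <- strsplit(sb, "")[[1]]
  # state: 0 = last column was a pair, 1 = gap in A (B consumed), 2 = gap in B
  rec <- function(i, j, state) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      best <- max(best, submat[ca[i], cb[j]] + rec(i + 1, j + 1, 0L))
    }
    if (j <= length(cb)) {   # gap in A
      cost <- if (state == 1L) ext else open + ext
      best <- max(best, -cost + rec(i, j + 1, 1L))
    }
    if (i <= length(ca)) {   # gap in B
      cost <- if (state == 2L) ext else open + ext
      best <- max(best, -cost + rec(i + 1, j, 2L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

# brute-force check of the three cut-eligibility conditions on one column
oracle_cut_ok <- function(ap, c, w = 1L) {
  cols <- ap$columns
  n <- nrow(cols)
  lo <- c - w; hi <- c + 1L + w
  if (lo < 1L || hi > n) return(FALSE)
  if (any(is.na(cols$a_pos[lo:hi])) || any(is.na(cols$b_pos[lo:hi])))
    return(FALSE)
  sa <- strsplit(ap$ss_a, "")[[1]]
  sb <- strsplit(ap$ss_b, "")[[1]]
  if (sa[cols$a_pos[c]] != "C" || sb[cols$b_pos[c]] != "C") return(FALSE)
  splits <- function(pos, ss) pos >= 1 && pos < length(ss) &&
    ss[pos] != "C" && ss[pos + 1] == ss[pos]
  !splits(cols$a_pos[c], sa) && !splits(cols$b_pos[c], sb)
}

# exhaustive search for the maximum number of cuts over eligible candidates,
# subject to the fragment-length constraints (recursion over ordered subsets)
oracle_max_cuts <- function(ap, cand, minl = 5L, maxl = 19L) {
  cols <- ap$columns
  ncols <- nrow(cols)
  seg <- function(from, to) {
    idx <- seq.int(from + 1L, to)
    c(sum(!is.na(cols$a_pos[idx])), sum(!is.na(cols$b_pos[idx])))
  }
  best <- -1L
  rec <- function(prev, k, internal) {
    # close the scheme here: last fragment is terminal (min length only)
    if (all(seg(prev, ncols) >= minl) && k > best) best <<- k
    for (cc in cand[cand > prev]) {
      len <- seg(prev, cc)
      if (any(len < minl)) next
      if (internal && any(len > maxl)) next    # internal fragment bound
      rec(cc, k + 1L, TRUE)
    }
  }
  rec(0L, 0L, FALSE)
  best   # max cuts; -1 if even the single-fragment scheme is infeasible
}

# brute-force hydrogen-bond detection over an explicit donor/acceptor roster
oracle_hbonds <- function(frame, donors, acceptors, max_dist = 3.5,
                          min_angle = 120) {
  a <- frame$atoms
  key <- function(r) paste(r$chain, r$res_seq, r$atom_name)
  out <- character(0)
  for (di in seq_len(nrow(donors))) {
    d <- a[a$chain == donors$chain[di] & a$res_seq == donors$res_seq[di] &
             a$atom_name == donors$atom_name[di], ]
    h <- a[a$chain == donors$chain[di] & a$res_seq == donors$res_seq[di] &
             a$atom_name == donors$h_name[di], ]
    if (!nrow(d) || !nrow(h)) next
    for (ai in seq_len(nrow(acceptors))) {
      acc <- a[a$chain == acceptors$chain[ai] &
                 a$res_seq == acceptors$res_seq[ai] &
                 a$atom_name == acceptors$atom_name[ai], ]
      if (!nrow(acc)) next
      if (d$res_seq == acc$res_seq && d$chain == acc$chain) next
      dist <- sqrt((d$x - acc$x)^2 + (d$y - acc$y)^2 + (d$z - acc$z)^2)
      if (dist > max_dist) next
      v1 <- c(d$x - h$x, d$y - h$y, d$z - h$z)
      v2 <- c(acc$x - h$x, acc$y - h$y, acc$z - h$z)
      ang <- acos(min(max(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) *
        180 / pi
      if (ang >= min_angle)
        out <- c(out, paste(key(d), key(acc), sep = "->"))
    }
  }
  sort(out)
}

# random amino-acid sequence for property tests
random_aa <- function(n, seed) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})
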
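test_that("all-coil parents yield candidates matching the brute-force conditions", {
  pp <- make_parent_pair(1, 10)
  ap <- align_parents(pp$a, pp$b, pp$ss_a, pp$ss_b)
  cand <- find_cut_candidates(ap)
  expect_equal(cand$column, 2:8)
  brute <- Filter(function(c) oracle_cut_ok(ap, c), seq_len(nrow(ap$columns)))
  expect_equal(cand$column, as.integer(brute))
})

test_that("an all-helix parent admits no cut sites", {
  pp <- make_parent_pair(2, 20, ss_layout = strrep("H", 20))
  ap <- align_parents(pp$a, pp$b, pp$ss_a, pp$ss_b)
  expect_equal(nrow(find_cut_candidates(ap)), 0)
})

test_that("coil columns adjacent to gaps are excluded", {
  # identical except one deletion in B inside a coil region
  pp <- make_parent_pair(3, 30, indels = 1L)
  ap <- align_parents(pp$a, pp$b, pp$ss_a, pp$ss_b)
  gap_cols <- which(is.na(ap$columns$a_pos) | is.na(ap$columns$b_pos))
  expect_length(gap_cols, 1)
  cand <- find_cut_candidates(ap)$column
  # a cut after c needs columns c-1..c+2 aligned: gaps exclude c in g-2..g+1
  expect_false(any(cand >= gap_cols - 2 & cand <= gap_cols + 1))
  brute <- Filter(function(c) oracle_cut_ok(ap, c), seq_len(nrow(ap$columns)))
  expect_equal(cand, as.integer(brute))
})

test_that("max_internal_count partitioning matches exhaustive enumeration", {
  layouts <- list(
    strrep("C", 40),
    strrep("C", 55),
    paste0("CCCCC", strrep("H", 8), "CCCC", strrep("E", 5), "CCCCCC",
           strrep("H", 10), "CCCCC"),
    ss_layout_for_fragments(5, block = 7, gap = 4, cap = 6))
  for (i in seq_along(layouts)) {
    lay <- layouts[[i]]
    pp <- make_parent_pair(100 + i, nchar(lay), lay, divergence_pct = 30)
    ap <- align_parents(pp$a, pp$b, pp$ss_a, pp$ss_b)
    params <- demarcation_params()
    scheme <- partition_fragments(ap, params)
    expect_length(validate_scheme(scheme, ap), 0)
    cand <- find_cut_candidates(ap, params)$column
    expect_equal(length(scheme$cut_columns),
                 oracle_max_cuts(ap, cand), info = paste("layout", i))
    # determinism
    scheme2 <- partition_fragments(ap, params)
    expect_identical(scheme$fragments, scheme2$fragments)
  }
})

test_that("fragment schemes tile both parents and respect SS and length bounds", {
  for (seed in 1:5) {
    lay <- ss_layout_for_fragments(4 + seed %% 3, block = 6 + seed, gap = 4,
                                   cap = 5)
    pp <- make_parent_pair(seed, nchar(lay), lay, divergence_pct = 35)
    ap <- align_parents(pp$a, pp$b, pp$ss_a, pp$ss_b)
    scheme <- partition_fragments(ap)
    expect_length(validate_scheme(scheme, ap), 0)
    fr <- scheme$fragments
    expect_equal(fr$a_start[1], 1)
    expect_equal(fr$a_end[nrow(fr)], nchar(pp$a$seq))
    expect_equal(fr$name, paste0("M", seq_len(nrow(fr))))
  }
})

test_that("target_count reproduces a ten-fragment scheme on a 10-feasible pair", {
  lay <- ss_layout_for_fragments(10)
  pp <- make_parent_pair(42, nchar(lay), lay, divergence_pct = 40)
  ap <- align_parents(pp$a, pp$b, pp$ss_a, pp$ss_b)
  scheme <- partition_fragments(
    ap, demarcation_params(objective = "target_count", target_count = 10))
  expect_equal(nrow(scheme$fragments), 10)
  expect_equal(scheme$fragments$name, paste0("M", 1:10))
  expect_length(validate_scheme(scheme, ap), 0)
  expect_equal(scheme$fragments$terminal, c(TRUE, rep(FALSE, 8), TRUE))
})

test_that("infeasible target counts fail with the achievable maximum", {
  pp <- make_parent_pair(5, 30)
  ap <- align_parents(pp$a, pp$b, pp$ss_a, pp$ss_b)
  expect_error(partition_fragments(
    ap, demarcation_params(objective = "target_count", target_count = 50)),
    "maximum achievable")
})

test_that("validate_scheme reports length and tiling violations on broken schemes", {
  lay <- ss_layout_for_fragments(5, block = 9, gap = 5, cap = 6)
  pp <- make_parent_pair(9, nchar(lay), lay)
  ap <- align_parents(pp$a, pp$b, pp$ss_a, pp$ss_b)
  scheme <- partition_fragments(ap)
  expect_length(validate_scheme(scheme, ap), 0)

  long <- scheme
  long$fragments$a_end[2] <- long$fragments$a_start[2] + 24   # 25-residue internal
  v <- validate_scheme(long, ap)
  expect_true(any(vapply(v, function(x) x$type == "length" &&
                           x$fragment == long$fragments$name[2], TRUE)))

  overlap <- scheme
  overlap$fragments$a_start[3] <- overlap$fragments$a_start[3] - 2
  v <- validate_scheme(overlap, ap)
  expect_true(any(vapply(v, function(x) x$type == "tiling", TRUE)))
})

test_that("scheme TSV round-trips through write_scheme/read_scheme", {
  lay <- ss_layout_for_fragments(6)
  pp <- make_parent_pair(12, nchar(lay), lay, divergence_pct = 20)
  ap <- align_parents(pp$a, pp$b, pp$ss_a, pp$ss_b)
  scheme <- partition_fragments(ap)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_scheme(scheme, f)
  back <- read_scheme(f, parent_a = "parentA", parent_b = "parentB")
  expect_equal(back$fragments$a_start, scheme$fragments$a_start)
  expect_equal(back$fragments$name, scheme$fragments$name)
})
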
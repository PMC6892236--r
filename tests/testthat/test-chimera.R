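# shared gap-free fixture: 10-fragment scheme over a designed layout
local_pair <- function(seed = 42) {
  lay <- ss_layout_for_fragments(10)
  pp <- make_parent_pair(seed, nchar(lay), lay, divergence_pct = 40)
  ap <- align_parents(pp$a, pp$b, pp$ss_a, pp$ss_b)
  scheme <- partition_fragments(
    ap, demarcation_params(objective = "target_count", target_count = 10))
  list(pp = pp, ap = ap, scheme = scheme)
}

test_that("zero-swap and full-swap constructs reproduce the parents", {
  fx <- local_pair()
  c0 <- generate_chimeras(fx$scheme, fx$ap, "parentA", character(0))[[1]]
  expect_equal(c0$sequence, fx$pp$a$seq)
  expect_equal(c0$name, "parentA")
  expect_true(all(strsplit(c0$provenance, "")[[1]] == "A"))

  call_ <- generate_chimeras(fx$scheme, fx$ap, "parentA")[[1]]   # all fragments
  expect_equal(call_$sequence, fx$pp$b$seq)                      # gap-free pair
  expect_true(all(strsplit(call_$provenance, "")[[1]] == "B"))
})

test_that("combinations-of three fragments yields the seven named constructs", {
  fx <- local_pair()
  cc <- generate_chimeras(fx$scheme, fx$ap, "parentA", c("M6", "M3", "M9"),
                          mode = "combinations")
  expect_equal(vapply(cc, `[[`, "", "name"),
               paste0("parentA-", c("M3", "M6", "M9", "M3/M6", "M3/M9",
                                    "M6/M9", "M3/M6/M9")))
  # reverse direction is first-class
  rev <- generate_chimeras(fx$scheme, fx$ap, "parentB", "M6")[[1]]
  expect_equal(rev$name, "parentB-M6")
  expect_equal(rev$donor, "parentA")
})

test_that("swapped intervals carry donor provenance and the rest recipient", {
  fx <- local_pair()
  cc <- generate_chimeras(fx$scheme, fx$ap, "parentA", c("M3", "M6"))[[1]]
  prov <- strsplit(cc$provenance, "")[[1]]
  fr <- fx$scheme$fragments
  for (i in seq_len(nrow(fr))) {
    span <- seq(fr$a_start[i], fr$a_end[i])   # gap-free: same on both parents
    expected <- if (fr$name[i] %in% c("M3", "M6")) "B" else "A"
    expect_true(all(prov[span] == expected), info = fr$name[i])
  }
})

test_that("swapping a set and swapping it back restores the original parent", {
  fx <- local_pair()
  for (set in list("M4", c("M2", "M7"), c("M3", "M6", "M9"))) {
    fwd <- generate_chimeras(fx$scheme, fx$ap, "parentA", set)[[1]]
    # independent reversal: re-substitute parent A residues over the swapped
    # intervals (valid because the pair is gap-free)
    seqv <- strsplit(fwd$sequence, "")[[1]]
    av <- strsplit(fx$pp$a$seq, "")[[1]]
    fr <- fx$scheme$fragments
    for (m in set) {
      i <- which(fr$name == m)
      seqv[fr$a_start[i]:fr$a_end[i]] <- av[fr$a_start[i]:fr$a_end[i]]
    }
    expect_equal(paste(seqv, collapse = ""), fx$pp$a$seq)
  }
})

test_that("name grammar round-trips and unknown fragments are rejected", {
  expect_equal(chimera_name("XylE", c("M6", "M3")), "XylE-M3/M6")
  p <- parse_chimera_name("XylE-M3/M6/M9")
  expect_equal(p$recipient, "XylE")
  expect_equal(p$fragments, c("M3", "M6", "M9"))
  expect_equal(parse_chimera_name("XYL10C")$fragments, character(0))
  fx <- local_pair()
  expect_error(generate_chimeras(fx$scheme, fx$ap, "parentA", "M99"),
               "unknown fragment")
  expect_error(generate_chimeras(fx$scheme, fx$ap, "nobody", "M1"),
               "recipient")
})

test_that("reverse translation inherits parent codons and round-trips", {
  fx <- local_pair()
  # build parent CDS by reverse-translating the parents themselves
  pa <- generate_chimeras(fx$scheme, fx$ap, "parentA", character(0))[[1]]
  cds_a <- reverse_translate(pa, ap = fx$ap)
  pb <- generate_chimeras(fx$scheme, fx$ap, "parentB", character(0))[[1]]
  cds_b <- reverse_translate(pb, ap = fx$ap)
  expect_equal(translate_dna(cds_a), fx$pp$a$seq)

  # no swaps + recipient CDS supplied -> output equals recipient CDS
  out <- reverse_translate(pa, cds_a = cds_a, cds_b = cds_b, ap = fx$ap)
  expect_equal(out$seq, cds_a$seq)

  # random constructs round-trip through the standard-code translation oracle
  for (set in list("M5", c("M2", "M8"))) {
    cc <- generate_chimeras(fx$scheme, fx$ap, "parentA", set)[[1]]
    dna <- reverse_translate(cc, cds_a = cds_a, cds_b = cds_b, ap = fx$ap)
    oracle <- as.character(Biostrings::translate(Biostrings::DNAString(dna$seq)))
    expect_equal(oracle, cc$sequence)
  }

  # mismatched CDS is rejected, naming the first discordant codon
  bad <- cds_a
  bad$seq <- paste0("GGG", substr(bad$seq, 4, nchar(bad$seq)))
  expect_error(reverse_translate(pa, cds_a = bad, ap = fx$ap),
               "first discordant codon GGG \\(#1")
})

test_that("single-residue constructs use the unique methionine codon", {
  x <- structure(list(name = "mini", sequence = "M", provenance = "A",
                      src_pos = 1L, recipient = "A", donor = "B",
                      recipient_label = "A", swapped = character(0)),
                 class = "chimera_construct")
  expect_equal(reverse_translate(x)$seq, "ATG")
})

test_that("Wallace melting temperatures follow the 2+4 closed form", {
  expect_equal(primer_tm("AAAA", "wallace"), 8)
  expect_equal(primer_tm("GGGGCCCC", "wallace"), 32)
  expect_error(primer_tm("ACGU", "wallace"), "ACGT")
})

test_that("nearest-neighbor Tm matches a hand-summed thermodynamic oracle", {
  oligo <- "AGCTTGCAACGGTCATAGGC"   # fixed 20-mer
  # independent recomputation: explicit per-step sums, SantaLucia 1998 unified
  dH <- c(AG = -7.8, GC = -9.8, CT = -7.8, TT = -7.9, TG = -8.5, GC2 = -9.8,
          CA = -8.5, AA = -7.9, AC = -8.4, CG = -10.6, GG = -8.0, GT = -8.4,
          TC = -8.2, CA2 = -8.5, AT = -7.2, TA = -7.2, AG2 = -7.8, GG2 = -8.0,
          GC3 = -9.8)
  dS <- c(-21.0, -24.4, -21.0, -22.2, -22.7, -24.4, -22.7, -22.2, -22.4,
          -27.2, -19.9, -22.4, -22.2, -22.7, -20.4, -21.3, -21.0, -19.9,
          -24.4)
  sum_dH <- sum(dH) + 2.3 + 0.1        # A/T start, G/C end initiation
  sum_dS <- sum(dS) + 4.1 - 2.8
  tm_expected <- sum_dH * 1000 / (sum_dS + 1.987 * log(5e-7 / 4)) - 273.15
  expect_equal(primer_tm(oligo, "nearest_neighbor"), tm_expected,
               tolerance = 1e-12)
})

test_that("junction primers span the junction and occur once in the construct", {
  fx <- local_pair()
  cc <- generate_chimeras(fx$scheme, fx$ap, "parentA", c("M3", "M6"))[[1]]
  dna <- reverse_translate(cc, ap = fx$ap)
  fr <- fx$scheme$fragments
  junctions <- 3L * fr$a_end[c(3, 6)]   # nt junction after swapped fragments
  pr <- suppressWarnings(
    design_overlap_primers(dna, junctions, tm_method = "nearest_neighbor",
                           tm_band = c(60, 95)))
  expect_equal(nrow(pr), 2)
  for (i in 1:2) {
    expect_equal(pr$reverse[i], as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(pr$forward[i]))))
    # forward primer covers the junction with min_flank on both sides
    hits <- gregexpr(pr$forward[i], dna$seq, fixed = TRUE)[[1]]
    expect_length(hits, 1)   # occurs exactly once
    expect_true(hits[1] <= junctions[i] - 14 &&
                  hits[1] + pr$overlap_len[i] - 1 >= junctions[i] + 15)
  }
  expect_error(design_overlap_primers(dna, junctions = 5), "min_flank")
})
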
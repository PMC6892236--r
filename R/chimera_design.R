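## Hybrid-sequence assembly for single and combinatorial fragment
## replacements in either direction, plus overlap-extension PCR primer design
## for the resulting genes.

## donor counterpart interval of a recipient fragment is alignment-mediated:
## the donor residues aligned to the fragment's columns, extended through
## interior gaps. With tiling schemes this is exactly the stored b interval.

.frag_indices <- function(names) as.integer(sub("^M", "", names))

#' Canonical chimera name
#'
#' `"<recipient>-M3/M6"` style: recipient id, then the swapped fragment
#' labels joined by `/` in ascending index order. An empty swap set names the
#' construct after the recipient alone.
#'
#' @param recipient Recipient parent id.
#' @param fragments Character vector of fragment names (`"M3"`, ...).
#' @return The canonical name string.
#' @export
chimera_name <- function(recipient, fragments) {
  if (!length(fragments)) return(recipient)
  fragments <- fragments[order(.frag_indices(fragments))]
  paste0(recipient, "-", paste(fragments, collapse = "/"))
}

#' Parse a canonical chimera name
#'
#' Inverse of [chimera_name()].
#'
#' @param name Name string.
#' @return List with `recipient` and `fragments` (character vector, ascending
#'   index order).
#' @export
parse_chimera_name <- function(name) {
  if (!grepl("-M\\d+(/M\\d+)*$", name))
    return(list(recipient = name, fragments = character(0)))
  recipient <- sub("-M\\d+(/M\\d+)*$", "", name)
  frags <- strsplit(sub("^.*?-(M\\d+(/M\\d+)*)$", "\\1", name), "/")[[1]]
  list(recipient = recipient, fragments = frags[order(.frag_indices(frags))])
}

#' Generate chimeric constructs by fragment replacement
#'
#' Builds hybrid sequences on a recipient backbone, substituting the donor's
#' alignment-mediated counterpart interval for every swapped fragment (so
#' construct length may change when the alignment has indels inside a
#' fragment). Every residue carries parent provenance (`"A"`/`"B"`) and its
#' position in its source parent.
#'
#' @param scheme A `fragment_scheme` from [partition_fragments()].
#' @param ap The `aligned_parents` the scheme was derived from.
#' @param recipient `"a"`/`"b"` or a parent id; the other parent is the donor.
#' @param fragments Character vector of fragment names to swap (interpreted
#'   per `mode`). Defaults to all fragments for `mode = "singles"`.
#' @param mode `"set"` (one construct carrying all named fragments),
#'   `"singles"` (one construct per named fragment), or `"combinations"`
#'   (all non-empty subsets of the named fragments). Output order is
#'   deterministic: ascending fragment index, then subset size.
#' @return List of `chimera_construct` objects (fields `name`, `sequence`,
#'   `provenance`, `src_pos`, `recipient`, `donor`, `swapped`).
#' @examples
#' # see make_parent_pair() for a self-contained fixture
#' @export
generate_chimeras <- function(scheme, ap, recipient,
                              fragments = scheme$fragments$name,
                              mode = c("set", "singles", "combinations")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scheme, "fragment_scheme"), inherits(ap, "aligned_parents"))
  unknown <- setdiff(fragments, scheme$fragments$name)
  if (length(unknown))
    stop("unknown fragment name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  fragments <- fragments[order(.frag_indices(fragments))]
  sets <- switch(mode,
    set = list(fragments),
    singles = lapply(fragments, identity),
    combinations = {
      k <- length(fragments)
      subsets <- list()
      for (size in seq_len(k)) {
        cmb <- utils::combn(fragments, size, simplify = FALSE)
        subsets <- c(subsets, cmb)
      }
      ## ascending fragment index, then subset size: sort by (size, indices)
      ord <- order(lengths(subsets),
                   vapply(subsets, function(s)
                     paste(sprintf("%04d", .frag_indices(s)), collapse = ""), ""))
      subsets[ord]
    })
  lapply(sets, function(s) .assemble_chimera(scheme, ap, recipient, s))
}

.resolve_recipient <- function(ap, recipient) {
  if (identical(recipient, "a") || identical(recipient, ap$parent_a$id)) "a"
  else if (identical(recipient, "b") || identical(recipient, ap$parent_b$id)) "b"
  else stop("recipient must be 'a', 'b', or a parent id", call. = FALSE)
}

.assemble_chimera <- function(scheme, ap, recipient, swapped) {
  side <- .resolve_recipient(ap, recipient)
  rec <- if (side == "a") ap$parent_a else ap$parent_b
  don <- if (side == "a") ap$parent_b else ap$parent_a
  rec_lab <- toupper(side)
  don_lab <- if (side == "a") "B" else "A"
  fr <- scheme$fragments
  seq_parts <- prov <- src <- list()
  for (i in seq_len(nrow(fr))) {
    use_donor <- fr$name[i] %in% swapped
    pre <- if (side == "a") c("a_", "b_") else c("b_", "a_")
    iv <- if (use_donor) c(fr[[paste0(pre[2], "start")]][i],
                           fr[[paste0(pre[2], "end")]][i])
          else c(fr[[paste0(pre[1], "start")]][i], fr[[paste0(pre[1], "end")]][i])
    source_seq <- if (use_donor) don$seq else rec$seq
    seq_parts[[i]] <- substr(source_seq, iv[1], iv[2])
    npos <- iv[2] - iv[1] + 1L
    prov[[i]] <- rep(if (use_donor) don_lab else rec_lab, npos)
    src[[i]] <- seq.int(iv[1], iv[2])
  }
  structure(list(name = chimera_name(rec$id, swapped),
                 sequence = paste(unlist(seq_parts), collapse = ""),
                 provenance = paste(unlist(prov), collapse = ""),
                 src_pos = unlist(src),
                 recipient = rec$id, donor = don$id,
                 recipient_label = rec_lab,
                 swapped = swapped[order(.frag_indices(swapped))]),
            class = "chimera_construct")
}

#' @export
print.chimera_construct <- function(x, ...) {
  donor_n <- sum(strsplit(x$provenance, "")[[1]] != x$recipient_label)
  cat(sprintf("<chimera_construct> %s: %d aa, %d donor residues (%s from %s)\n",
              x$name, nchar(x$sequence), donor_n,
              if (length(x$swapped)) paste(x$swapped, collapse = "/") else "none",
              x$donor))
  invisible(x)
}

## ---- reverse translation ---------------------------------------------------

## most-frequent codon per amino acid (E. coli K-12 usage), used when no
## parent CDS is available for a residue
.PREFERRED_CODONS <- c(
  A = "GCG", C = "TGC", D = "GAT", E = "GAA", F = "TTT", G = "GGC",
  H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAC",
  P = "CCG", Q = "CAG", R = "CGT", S = "AGC", T = "ACC", V = "GTG",
  W = "TGG", Y = "TAT")

#' Translate a DNA sequence (standard genetic code)
#'
#' @param dna DNA string or `seq_record`; length must be a multiple of 3.
#' @return Amino-acid string (stop codons become `*`).
#' @export
translate_dna <- function(dna) {
  if (inherits(dna, "seq_record")) dna <- dna$seq
  if (nchar(dna) %% 3 != 0)
    stop("CDS length is not a multiple of 3", call. = FALSE)
  codons <- substring(dna, seq(1, nchar(dna), 3), seq(3, nchar(dna), 3))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

.check_cds <- function(cds, parent, what) {
  if (is.null(cds)) return(invisible(NULL))
  dna <- if (inherits(cds, "seq_record")) cds$seq else toupper(cds)
  aa <- translate_dna(sub("(TAA|TAG|TGA)$", "", dna))
  if (aa != parent$seq) {
    codons <- substring(dna, seq(1, nchar(dna), 3), seq(3, nchar(dna), 3))
    i <- which(strsplit(aa, "")[[1]] != strsplit(parent$seq, "")[[1]])[1]
    stop(sprintf("%s CDS does not translate to parent %s: first discordant codon %s (#%d, encodes %s, expected %s)",
                 what, parent$id, codons[i], i,
                 substr(aa, i, i), substr(parent$seq, i, i)), call. = FALSE)
  }
  dna
}

#' Reverse-translate a chimeric construct to DNA
#'
#' Each residue inherits its codon from the CDS of the parent it came from
#' when that CDS is supplied (matching how constructs are actually assembled
#' from the two parent genes); residues without a source CDS fall back to a
#' bundled preferred-codon table (most frequent E. coli codons). The output
#' always translates back to the construct's amino-acid sequence, and the
#' presence of internal EcoRI/NotI sites (the cloning sites) is reported as a
#' warning.
#'
#' @param construct A `chimera_construct`.
#' @param cds_a,cds_b Optional parent CDS (`seq_record` DNA or string); each
#'   must translate exactly to its parent's amino-acid sequence (a trailing
#'   stop codon is allowed).
#' @param codon_table Genetic code used for consistency checks; only
#'   `"standard"` is supported.
#' @param ap The `aligned_parents` (used only to check CDS/parent
#'   consistency); optional when no CDS is given.
#' @return A `seq_record` of type `"DNA"` named after the construct.
#' @export
reverse_translate <- function(construct, cds_a = NULL, cds_b = NULL,
                              codon_table = "standard", ap = NULL) {
  stopifnot(inherits(construct, "chimera_construct"))
  if (!identical(codon_table, "standard"))
    stop("only the standard genetic code is supported", call. = FALSE)
  dna_a <- dna_b <- NULL
  if (!is.null(cds_a) || !is.null(cds_b)) {
    if (is.null(ap)) stop("supply `ap` so parent CDS can be validated",
                          call. = FALSE)
    dna_a <- .check_cds(cds_a, ap$parent_a, "cds_a")
    dna_b <- .check_cds(cds_b, ap$parent_b, "cds_b")
  }
  aa <- strsplit(construct$sequence, "")[[1]]
  prov <- strsplit(construct$provenance, "")[[1]]
  codons <- character(length(aa))
  for (i in seq_along(aa)) {
    src_dna <- if (prov[i] == "A") dna_a else dna_b
    if (!is.null(src_dna)) {
      p <- construct$src_pos[i]
      codons[i] <- substr(src_dna, 3L * p - 2L, 3L * p)
    } else {
      codons[i] <- .PREFERRED_CODONS[[aa[i]]]
    }
  }
  dna <- paste(codons, collapse = "")
  stopifnot(translate_dna(dna) == construct$sequence)
  for (site in c(EcoRI = "GAATTC", NotI = "GCGGCCGC")[c(
    grepl("GAATTC", dna), grepl("GCGGCCGC", dna))])
    warning("construct DNA contains an internal cloning site: ", site,
            call. = FALSE)
  seq_record(construct$name, dna, type = "DNA",
             description = "reverse-translated chimeric construct")
}

## ---- primer design ---------------------------------------------------------

#' Reverse complement of a DNA string
#' @param dna DNA string.
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Oligonucleotide melting temperature
#'
#' `method = "wallace"`: the 2+4 rule, `Tm = 2(A+T) + 4(G+C)` degrees C.
#' `method = "nearest_neighbor"`: SantaLucia (1998) unified nearest-neighbor
#' thermodynamics at the 1 M Na+ reference, `Tm = dH / (dS + R ln(C_T/4)) -
#' 273.15` with total oligo concentration `conc_m` (default 5e-7 M,
#' non-self-complementary duplex).
#'
#' @param seq Primer sequence 5'->3'.
#' @param method `"nearest_neighbor"` or `"wallace"`.
#' @param conc_m Total strand concentration (mol/L), nearest-neighbor only.
#' @return Tm in degrees C.
#' @export
primer_tm <- function(seq, method = c("nearest_neighbor", "wallace"),
                      conc_m = 5e-7) {
  method <- match.arg(method)
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) stop("primer must be ACGT only", call. = FALSE)
  chars <- strsplit(seq, "")[[1]]
  if (method == "wallace") {
    return(2 * sum(chars %in% c("A", "T")) + 4 * sum(chars %in% c("G", "C")))
  }
  nn <- .NN_PARAMS
  dH <- 0; dS <- 0
  for (i in seq_len(length(chars) - 1L)) {
    step <- paste0(chars[i], chars[i + 1L])
    dH <- dH + nn$dH[[step]]
    dS <- dS + nn$dS[[step]]
  }
  for (end in c(chars[1], chars[length(chars)])) {
    if (end %in% c("G", "C")) { dH <- dH + 0.1;  dS <- dS - 2.8 }
    else                      { dH <- dH + 2.3;  dS <- dS + 4.1 }
  }
  R <- 1.987  # cal / (mol K)
  dH * 1000 / (dS + R * log(conc_m / 4)) - 273.15
}

## SantaLucia 1998 unified NN parameters: dH kcal/mol, dS cal/(mol K)
.NN_PARAMS <- local({
  dH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
          GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
          CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
  dS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
          TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
          GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
          CC = -19.9)
  list(dH = as.list(dH), dS = as.list(dS))
})

#' Design overlap-extension PCR junction primers
#'
#' For each junction (a nucleotide position after which two fragments meet),
#' emits a forward primer (the sense-strand window spanning the junction) and
#' a reverse primer (the reverse complement of the same window), starting at
#' `min_flank` nucleotides on each side and growing the window symmetrically
#' until both melting temperatures enter `tm_band` or the window reaches 40
#' nt (then a best-effort pair is returned, flagged, with a warning).
#'
#' @param dna A `seq_record` (DNA) or DNA string.
#' @param junctions Integer vector of junction positions (nt; each must be at
#'   least `min_flank` from both ends).
#' @param min_flank Minimum flank on each side of the junction (default 15 nt).
#' @param tm_method Passed to [primer_tm()].
#' @param tm_band Length-2 numeric, acceptable Tm range in degrees C.
#' @return data.frame with columns `junction`, `forward`, `reverse`, `tm_f`,
#'   `tm_r`, `overlap_len`, `in_band`.
#' @export
design_overlap_primers <- function(dna, junctions, min_flank = 15,
                                   tm_method = c("nearest_neighbor", "wallace"),
                                   tm_band = c(55, 65)) {
  tm_method <- match.arg(tm_method)
  if (inherits(dna, "seq_record")) dna <- dna$seq
  dna <- toupper(dna)
  n <- nchar(dna)
  out <- lapply(junctions, function(j) {
    if (j < min_flank || j > n - min_flank)
      stop(sprintf("junction %d is closer than min_flank (%d nt) to a sequence end",
                   j, min_flank), call. = FALSE)
    f <- min_flank
    repeat {
      lo <- j - f + 1L; hi <- j + f
      lo <- max(lo, 1L); hi <- min(hi, n)
      window <- substr(dna, lo, hi)
      tm_f <- primer_tm(window, tm_method)
      rev <- reverse_complement(window)
      tm_r <- primer_tm(rev, tm_method)
      in_band <- tm_f >= tm_band[1] && tm_f <= tm_band[2] &&
        tm_r >= tm_band[1] && tm_r <= tm_band[2]
      ## Tm only grows with window length: stop once over the band too
      over_band <- tm_f > tm_band[2] && tm_r > tm_band[2]
      if (in_band || over_band || nchar(window) >= 40L ||
          (lo == 1L && hi == n)) {
        if (!in_band)
          warning(sprintf("junction %d: tm_band [%g, %g] unreachable; best-effort primers returned",
                          j, tm_band[1], tm_band[2]), call. = FALSE)
        return(data.frame(junction = j, forward = window, reverse = rev,
                          tm_f = tm_f, tm_r = tm_r,
                          overlap_len = nchar(window), in_band = in_band))
      }
      f <- f + 1L
    }
  })
  do.call(rbind, out)
}
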
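## Readers/writers for the external formats the toolkit touches: FASTA,
## PDB (single- and multi-model), delimited assay tables. Parsing of the
## standard formats is delegated to Biostrings / bio3d; this layer adds the
## validation contracts the rest of the package relies on.

.AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.DNA_ALPHABET <- c("A", "C", "G", "T")

#' Sequence record
#'
#' A minimal container for a named biological sequence.
#'
#' @param id Record identifier (no whitespace).
#' @param seq Sequence string; uppercased on construction. Amino-acid records
#'   use the 20 standard one-letter codes, DNA records use ACGT.
#' @param type `"AA"` or `"DNA"`.
#' @param description Free-text description (may be empty).
#'
#' @return An object of class `seq_record` with fields `id`, `seq`, `type`,
#'   `description`.
#' @examples
#' seq_record("xynA", "MKVLT")
#' @export
seq_record <- function(id, seq, type = c("AA", "DNA"), description = "") {
  type <- match.arg(type)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("sequence must be non-empty", call. = FALSE)
  if (grepl("[[:space:]]", seq)) stop("sequence contains whitespace", call. = FALSE)
  .check_alphabet(seq, type, id)
  structure(list(id = id, seq = seq, type = type, description = description),
            class = "seq_record")
}

.check_alphabet <- function(seq, type, id) {
  alpha <- if (type == "AA") .AA_ALPHABET else .DNA_ALPHABET
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% alpha)
  if (length(bad)) {
    stop(sprintf("record '%s': illegal %s residue '%s' at position %d",
                 id, type, chars[bad[1]], bad[1]), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record %s> %s, %d residues\n", x$type, x$id, nchar(x$seq)))
  s <- x$seq
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(" ", s, "\n")
  invisible(x)
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file (one or more records).
#' @param type Molecule type of the records, `"AA"` (default) or `"DNA"`.
#'
#' @return A list of [seq_record()] objects in file order; sequences are
#'   uppercased. An empty file is a format error; characters outside the
#'   declared alphabet raise an error naming the offending symbol and its
#'   position.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA format error in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("FASTA format error: no records in '", path, "'",
                              call. = FALSE)
  headers <- names(set)
  lapply(seq_along(set), function(i) {
    h <- strsplit(headers[i], "[[:space:]]+")[[1]]
    desc <- sub("^\\S+\\s*", "", headers[i])
    seq_record(h[1], as.character(set[[i]]), type = type, description = desc)
  })
}

#' Write sequence records as FASTA
#'
#' @param records A `seq_record` or list of them.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  if (inherits(records, "seq_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    header <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    writeLines(paste0(">", header), con)
    s <- r$seq
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

## ---- PDB ------------------------------------------------------------------

#' Structure model
#'
#' One model (frame) of a structure: a flat atom table. `(chain, res_seq,
#' atom_name)` must be unique within a model and coordinates finite.
#'
#' @param atoms data.frame with columns `chain`, `res_seq`, `res_name`,
#'   `atom_name`, `element`, `x`, `y`, `z`.
#' @param model_index Integer model number (>= 0).
#' @param source Provenance string (e.g. file path).
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, model_index = 0L, source = "") {
  need <- c("chain", "res_seq", "res_name", "atom_name", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  atoms <- atoms[, need]
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in structure model", call. = FALSE)
  key <- paste(atoms$chain, atoms$res_seq, atoms$atom_name)
  if (anyDuplicated(key))
    stop("duplicate (chain, res_seq, atom_name) in model: ",
         key[which(duplicated(key))[1]], call. = FALSE)
  structure(list(model_index = as.integer(model_index), atoms = atoms,
                 source = source), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model #%d> %d atoms, %d residues, chains: %s\n",
              x$model_index, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$res_seq))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Read a PDB file
#'
#' Fixed-column parsing of ATOM/HETATM records (wwPDB v3.3 layout) via
#' \pkg{bio3d}. Alternate locations other than blank/'A' are dropped with a
#' warning; insertion codes are rejected so that residue numbering stays
#' unambiguous for fragment demarcation.
#'
#' @param path Path to a PDB file.
#' @param model `"all"` (default) or a 1-based model number. Multi-model files
#'   yield one [structure_model()] per MODEL block.
#' @return A `structure_model` (single model requested or present) or a list
#'   of them.
#' @export
read_pdb <- function(path, model = "all") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  .prevalidate_pdb(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE,
                                          verbose = FALSE))
  at <- pdb$atom
  if (any(!is.na(at$insert) & nzchar(at$insert)))
    stop("insertion codes are not supported (found at residue ",
         at$resno[which(!is.na(at$insert))[1]], ")", call. = FALSE)
  nmod <- nrow(pdb$xyz)
  base <- data.frame(chain = ifelse(is.na(at$chain), "", at$chain),
                     res_seq = at$resno, res_name = at$resid,
                     atom_name = at$elety,
                     element = ifelse(is.na(at$elesy), substr(at$elety, 1, 1), at$elesy),
                     stringsAsFactors = FALSE)
  build <- function(i) {
    xyz <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
    a <- base
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    structure_model(a, model_index = i, source = path)
  }
  if (identical(model, "all")) {
    models <- lapply(seq_len(nmod), build)
    if (nmod == 1L) models[[1]] else models
  } else {
    model <- as.integer(model)
    if (is.na(model) || model < 1L || model > nmod)
      stop(sprintf("model %s not present (file has %d model(s))", model, nmod),
           call. = FALSE)
    build(model)
  }
}

## light structural scan so malformed fixed-width lines fail with a line number
.prevalidate_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(rec)
  if (!length(idx)) stop("no ATOM/HETATM records in '", path, "'", call. = FALSE)
  for (i in idx) {
    l <- lines[i]
    if (nchar(l) < 54)
      stop(sprintf("malformed PDB line %d (shorter than coordinate fields)", i),
           call. = FALSE)
    coords <- suppressWarnings(as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                                            substr(l, 47, 54))))
    if (any(is.na(coords)))
      stop(sprintf("malformed PDB line %d: non-numeric coordinate field", i),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Write one or more structure models as a PDB file
#'
#' Fixed-column ATOM records; multiple models are wrapped in MODEL/ENDMDL
#' blocks. Coordinates are written at the format's 3-decimal precision.
#'
#' @param models A `structure_model` or list of them (identical rosters
#'   recommended for trajectory-style files).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(models, path) {
  if (inherits(models, "structure_model")) models <- list(models)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1L
  for (m in seq_along(models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    a <- models[[m]]$atoms
    name4 <- ifelse(nchar(a$atom_name) >= 4, substr(a$atom_name, 1, 4),
                    sprintf(" %-3s", a$atom_name))
    writeLines(sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                       seq_len(nrow(a)), name4, a$res_name, a$chain, a$res_seq,
                       a$x, a$y, a$z, a$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## ---- assay tables ---------------------------------------------------------

.ASSAY_SCHEMAS <- list(
  kinetics     = c("substrate_mg_per_mL", "rate"),
  thermal_T50  = c("temperature_C", "residual_pct"),
  thermal_decay = c("time_h", "residual_pct"),
  synergy      = c("time_h", "both", "cellulase_only", "xylanase_only")
)

#' Read a delimited assay table
#'
#' Comma-delimited by default; tab accepted by sniffing the header line.
#' Leading `# key: value` comment lines are collected as metadata (assay
#' conditions such as pH or temperature are recorded verbatim, never
#' inferred). Rows are returned sorted ascending by the independent variable
#' (the first required column of the assay kind).
#'
#' Required columns by kind: `kinetics` (`substrate_mg_per_mL`, `rate`),
#' `thermal_T50` (`temperature_C`, `residual_pct`), `thermal_decay`
#' (`time_h`, `residual_pct`), `synergy` (`time_h`, `both`,
#' `cellulase_only`, `xylanase_only`; a `control` arm is optional).
#'
#' @param path Path to the delimited file.
#' @param kind One of `"kinetics"`, `"thermal_T50"`, `"thermal_decay"`,
#'   `"synergy"`.
#' @return A data.frame of class `assay_table` with attributes `kind` and
#'   `metadata` (named character vector).
#' @export
read_assay_table <- function(path, kind = c("kinetics", "thermal_T50",
                                            "thermal_decay", "synergy")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body)) stop("assay table '", path, "' is empty", call. = FALSE)
  sep <- if (grepl("\t", body[1])) "\t" else ","
  df <- utils::read.table(text = body, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  metadata <- character(0)
  if (length(meta_lines)) {
    kv <- regmatches(meta_lines, regexec("^#\\s*([^:]+):\\s*(.*)$", meta_lines))
    kv <- kv[lengths(kv) == 3]
    metadata <- stats::setNames(vapply(kv, `[`, "", 3),
                                trimws(vapply(kv, `[`, "", 2)))
  }
  required <- .ASSAY_SCHEMAS[[kind]]
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("assay table kind '%s' requires columns {%s}; missing: %s",
                 kind, paste(required, collapse = ", "),
                 paste(miss, collapse = ", ")), call. = FALSE)
  for (cn in names(df)) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]) & nzchar(trimws(df[[cn]])))
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                   bad[1], cn, df[[cn]][bad[1]]), call. = FALSE)
    df[[cn]] <- v
  }
  if (!all(vapply(df, function(v) all(is.finite(v) | is.na(v)), TRUE)))
    stop("non-finite value in assay table", call. = FALSE)
  df <- df[order(df[[required[1]]]), , drop = FALSE]
  rownames(df) <- NULL
  assay_table(df, kind = kind, metadata = metadata)
}

#' Construct an assay table from a data.frame
#'
#' @param df data.frame with the required columns for `kind` (see
#'   [read_assay_table()]).
#' @param kind Assay kind.
#' @param metadata Named character vector of assay conditions.
#' @return The data.frame, classed `assay_table`, sorted by the independent
#'   variable.
#' @export
assay_table <- function(df, kind = c("kinetics", "thermal_T50",
                                     "thermal_decay", "synergy"),
                        metadata = character(0)) {
  kind <- match.arg(kind)
  required <- .ASSAY_SCHEMAS[[kind]]
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  df <- df[order(df[[required[1]]]), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, kind = kind, metadata = metadata,
            class = c("assay_table", "data.frame"))
}

#' Write an assay table to a delimited file
#'
#' @param x An `assay_table` (or plain data.frame).
#' @param path Output path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_assay_table <- function(x, path, sep = ",") {
  con <- file(path, "w")
  on.exit(close(con))
  md <- attr(x, "metadata")
  if (length(md)) writeLines(sprintf("# %s: %s", names(md), md), con)
  utils::write.table(as.data.frame(x), con, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
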
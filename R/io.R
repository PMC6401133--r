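# Readers and writers for the standard formats the stack consumes and
# produces: PDB (via bio3d), FASTA/aligned FASTA (via Biostrings), A3M,
# CCMPred flat matrices, PSI-BLAST ASCII PSSMs, CASP RR records, dense
# matrix files and restraint tables.

# three-letter -> one-letter amino-acid code (bio3d's aa321 handles this,
# but we keep control over the X fallback)
.aa321 <- function(res3) {
  out <- suppressWarnings(bio3d::aa321(res3))
  out[is.na(out) | !(out %in% .AA20)] <- "X"
  out
}

#' Read residue coordinates from a PDB file
#'
#' Parses ATOM records with [bio3d::read.pdb()], selects one chain (default:
#' the first polymer chain), the first model of multi-model files and the
#' highest-occupancy alternate location, renumbers residues sequentially,
#' and returns the contact atom (C-beta; C-alpha for glycine and for
#' residues lacking a C-beta) plus the side-chain center of mass per
#' residue. Residues with neither C-beta nor C-alpha are flagged missing.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier; `NULL` selects the first polymer chain.
#' @return A [residue_coords()] with the chain sequence attached.
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  if (!nrow(atoms)) stop("no ATOM records in ", path)
  if (is.null(chain)) chain <- atoms$chain[1L]
  atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  if (!nrow(atoms)) stop("chain '", chain, "' not found in ", path)
  # highest-occupancy altloc per atom name within a residue
  atoms$alt[is.na(atoms$alt)] <- ""
  key <- paste(atoms$resno, atoms$insert, atoms$elety)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(ii) {
    ii[which.max(atoms$o[ii])]
  }), use.names = FALSE)
  atoms <- atoms[sort(keep), , drop = FALSE]

  resid_key <- paste(atoms$resno, atoms$insert)
  res_order <- unique(resid_key)
  L <- length(res_order)
  contact <- matrix(NA_real_, L, 3L)
  com <- matrix(NA_real_, L, 3L)
  seq3 <- character(L)
  backbone <- c("N", "CA", "C", "O", "OXT")
  for (r in seq_len(L)) {
    ra <- atoms[resid_key == res_order[r], , drop = FALSE]
    seq3[r] <- ra$resid[1L]
    xyz <- as.matrix(ra[, c("x", "y", "z")])
    cb <- which(ra$elety == "CB")
    ca <- which(ra$elety == "CA")
    if (length(cb)) contact[r, ] <- xyz[cb[1L], ]
    else if (length(ca)) contact[r, ] <- xyz[ca[1L], ]
    side <- which(!(ra$elety %in% backbone) & substr(ra$elety, 1L, 1L) != "H")
    if (length(side)) com[r, ] <- colMeans(xyz[side, , drop = FALSE])
    else if (length(ca)) com[r, ] <- xyz[ca[1L], ]
  }
  sequence <- paste(.aa321(seq3), collapse = "")
  residue_coords(contact, sidechain_com = com,
                 resolved = !apply(is.na(contact), 1L, any),
                 sequence = sequence)
}

#' Write a minimal PDB file
#'
#' Emits CA and CB ATOM records for a (typically synthetic) chain so that
#' fixtures exercise the real PDB reader. Glycines and residues whose `cb`
#' row is `NA` get only a CA record; residues with an all-`NA` `ca` row are
#' omitted (missing from the structure).
#'
#' @param ca L x 3 matrix of C-alpha coordinates.
#' @param cb L x 3 matrix of C-beta coordinates (rows may be `NA`).
#' @param sequence Amino-acid string of length L.
#' @param path Output file.
#' @param chain Chain identifier (single character).
#' @return `path`, invisibly.
#' @export
write_pdb_minimal <- function(ca, cb, sequence, path, chain = "A") {
  ca <- as.matrix(ca); cb <- as.matrix(cb)
  L <- nrow(ca)
  stopifnot(ncol(ca) == 3L, nrow(cb) == L, ncol(cb) == 3L,
            nchar(sequence) == L)
  aa <- strsplit(toupper(sequence), "")[[1]]
  aa3 <- vapply(aa, function(a) {
    v <- suppressWarnings(bio3d::aa123(a))
    if (is.na(v)) "UNK" else v
  }, character(1L))
  lines <- character(0L)
  serial <- 0L
  fmt <- "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00"
  for (r in seq_len(L)) {
    if (anyNA(ca[r, ])) next
    serial <- serial + 1L
    lines <- c(lines, sprintf(fmt, serial, "CA", aa3[r], chain, r,
                              ca[r, 1L], ca[r, 2L], ca[r, 3L]))
    if (aa[r] != "G" && !anyNA(cb[r, ])) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(fmt, serial, "CB", aa3[r], chain, r,
                                cb[r, 1L], cb[r, 2L], cb[r, 3L]))
    }
  }
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Read a multiple sequence alignment
#'
#' Accepts aligned FASTA or A3M. In A3M input, lowercase letters are
#' insertions relative to the target and are dropped, so all rows align to
#' the target's columns. The first row must be the ungapped target.
#'
#' @param path Alignment file.
#' @param format `"auto"` (by extension), `"fasta"` or `"a3m"`.
#' @return An `alignment` object: list with `seqs` (character matrix,
#'   N x L), `ids`, `depth`, `width`.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "a3m")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.a3m$", path, ignore.case = TRUE)) "a3m" else "fasta"
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA headers in ", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1L), 1L)
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(k) {
    paste(lines[starts[k]:ends[k]], collapse = "")
  }, character(1L))
  if (format == "a3m") seqs <- gsub("[a-z.]", "", seqs)
  seqs <- toupper(seqs)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("alignment rows differ in width (", paste(unique(widths), collapse = ", "),
         "); not a valid alignment")
  alignment(seqs, ids = ids)
}

#' Construct an alignment object
#'
#' @param seqs Character vector of aligned sequences (21-letter alphabet:
#'   20 amino acids plus `-`; `.` is converted to `-`, unknown letters to
#'   `X`). The first row is the ungapped target.
#' @param ids Row identifiers.
#' @return An object of class `alignment`.
#' @export
alignment <- function(seqs, ids = NULL) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  seqs <- chartr(".", "-", toupper(seqs))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) stop("all alignment rows must share one width")
  m <- do.call(rbind, strsplit(seqs, ""))
  m[!(m %in% c(.AA20, "-", "X"))] <- "X"
  if (any(m[1L, ] == "-"))
    stop("first alignment row must be the ungapped target")
  structure(list(seqs = m, ids = ids, depth = nrow(m), width = ncol(m)),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> depth %d x width %d (target: %s)\n",
              x$depth, x$width, x$ids[1L]))
  invisible(x)
}

#' Write an aligned-FASTA alignment
#'
#' @param aln An [alignment()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_msa <- function(aln, path) {
  stopifnot(inherits(aln, "alignment"))
  seqs <- apply(aln$seqs, 1L, paste, collapse = "")
  x <- Biostrings::AAStringSet(seqs)
  names(x) <- aln$ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA sequence as a protein record
#'
#' @param path FASTA file; the first record is used.
#' @return A [protein_record()].
#' @export
read_fasta_record <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  if (!length(x)) stop("no sequences in ", path)
  seq <- as.character(x[[1L]])
  seq <- gsub("[^A-Za-z]", "", seq)
  seq <- gsub("[^ACDEFGHIKLMNPQRSTVWYX]", "X", toupper(seq))
  protein_record(names(x)[1L], seq)
}

#' Write a protein record as FASTA
#'
#' @param record A [protein_record()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta_record <- function(record, path) {
  x <- Biostrings::AAStringSet(record$sequence)
  names(x) <- record$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a CCMPred-style coevolution score matrix
#'
#' The flat-matrix dialect: L whitespace-separated rows of L floats. The
#' matrix is symmetrized as (M + t(M))/2 and the diagonal zeroed.
#'
#' @param path Matrix file.
#' @param L Expected dimension (e.g. the target length); checked if given.
#' @return L x L numeric matrix.
#' @export
read_ccmpred <- function(path, L = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty coevolution matrix file: ", path)
  rows <- strsplit(trimws(lines), "\\s+")
  n <- length(rows)
  lens <- lengths(rows)
  if (any(lens != n)) {
    bad <- which(lens != n)[1L]
    stop("ragged coevolution matrix: row ", bad, " has ", lens[bad],
         " values, expected ", n)
  }
  vals <- suppressWarnings(lapply(rows, as.numeric))
  for (r in seq_len(n)) {
    if (anyNA(vals[[r]])) {
      stop("non-numeric token in coevolution matrix at row ", r,
           ", column ", which(is.na(vals[[r]]))[1L])
    }
  }
  M <- do.call(rbind, vals)
  if (!is.null(L) && n != L)
    stop("coevolution matrix is ", n, " x ", n,
         " but the sequence length is ", L)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  M
}

#' Write a coevolution matrix in the flat-matrix dialect
#'
#' @param M Square numeric matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ccmpred <- function(M, path) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  writeLines(apply(M, 1L, function(r) paste(sprintf("%.6g", r), collapse = "\t")),
             path)
  invisible(path)
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the 20-column log-odds block of `psiblast -out_ascii_pssm` output
#' and converts it to a positional probability profile via a softmax of the
#' half-bit scores.
#'
#' @param path PSSM file.
#' @return List with `profile` (L x 20 probabilities, columns in
#'   alphabetical one-letter order), `scores` (raw log-odds) and `sequence`.
#' @export
read_pssm <- function(path) {
  lines <- readLines(path)
  hdr_i <- grep("^\\s*A\\s+R\\s+N\\s+D", lines)[1L]
  if (is.na(hdr_i)) stop("not a PSI-BLAST ASCII PSSM: ", path)
  cols <- strsplit(trimws(lines[hdr_i]), "\\s+")[[1L]][1:20]
  body <- lines[-seq_len(hdr_i)]
  body <- body[grepl("^\\s*\\d+\\s+[A-Z]", body)]
  toks <- strsplit(trimws(body), "\\s+")
  seq <- vapply(toks, `[`, character(1L), 2L)
  scores <- t(vapply(toks, function(tk) as.numeric(tk[3:22]), numeric(20L)))
  colnames(scores) <- cols
  scores <- scores[, .AA20, drop = FALSE]   # alphabetical order
  prof <- exp(scores * log(2) / 2)          # half-bit log-odds
  prof <- prof / rowSums(prof)
  list(profile = prof, scores = scores, sequence = paste(seq, collapse = ""))
}

#' Write predictions as CASP RR records
#'
#' One line per pair: `i j 0 8 p` with 1-based indices, sorted by
#' descending probability.
#'
#' @param pred Symmetric probability matrix (or `prediction_map`).
#' @param path Output file.
#' @param cutoff Minimum probability for a pair to be written (default 0:
#'   all upper-triangle pairs with p > 0).
#' @param sequence Optional target sequence written as a leading comment.
#' @return `path`, invisibly.
#' @export
write_rr <- function(pred, path, cutoff = 0, sequence = NULL) {
  pred <- as_prob_matrix(pred)
  idx <- which(upper.tri(pred) & pred > cutoff, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1L], j = idx[, 2L], p = pred[idx])
  df <- df[order(-df$p, df$i, df$j), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(sequence)) writeLines(paste0("# ", sequence), con)
  writeLines(sprintf("%d %d 0 8 %.6f", df$i, df$j, df$p), con)
  invisible(path)
}

#' Read CASP RR records into a probability matrix
#'
#' @param path RR file (`i j 0 8 p` lines; comments ignored).
#' @param L Target length (matrix dimension).
#' @return L x L symmetric probability matrix.
#' @export
read_rr <- function(path, L) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^[#A-Za-z]", lines)]
  P <- matrix(0, L, L)
  for (ln in lines) {
    tk <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(tk) < 5L) stop("malformed RR line: ", ln)
    i <- as.integer(tk[1L]); j <- as.integer(tk[2L]); p <- as.numeric(tk[5L])
    if (is.na(i) || is.na(j) || is.na(p)) stop("malformed RR line: ", ln)
    if (i < 1L || j < 1L || i > L || j > L)
      stop("RR indices out of range in line: ", ln)
    P[i, j] <- p; P[j, i] <- p
  }
  P
}

#' Write a dense probability or score matrix
#'
#' @param M Numeric matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dense_matrix <- function(M, path) {
  write.table(format(M, digits = 7L, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Cache a feature tensor keyed by target id
#'
#' Feature tensors are expensive to rebuild; this stores them as RDS files
#' named by target id under a cache directory.
#'
#' @param tensor Feature tensor (or any R object).
#' @param id Target id.
#' @param dir Cache directory (created if needed).
#' @return The cache file path, invisibly.
#' @export
cache_features <- function(tensor, id, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(dir, paste0(id, ".rds"))
  saveRDS(tensor, f)
  invisible(f)
}

#' Load a cached feature tensor
#'
#' @param id Target id.
#' @param dir Cache directory.
#' @return The cached object, or `NULL` if absent.
#' @export
load_cached_features <- function(id, dir) {
  f <- file.path(dir, paste0(id, ".rds"))
  if (!file.exists(f)) return(NULL)
  readRDS(f)
}
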
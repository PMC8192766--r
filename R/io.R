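#' @include AllClasses.R constructors.R
NULL

## ---- RR contact-list dialect -------------------------------------------
## One pair per line: "i j d_low d_high probability". Prediction files may
## carry arbitrary non-numeric header/sequence lines, which are ignored on
## read. True contact maps add a first header line "L <int> KIND <intra|inter>"
## so kind and chain length survive a round trip.

#' Read predictions in CASP RR dialect
#'
#' Accepts whitespace-separated records `i j d_low d_high prob`; any line
#' whose first token is not an integer (sequence lines, `PFRMAT`/`TARGET`
#' headers, comments) is skipped. Pairs are canonicalized to `i < j`.
#'
#' @param file path to an RR file.
#' @param L monomer length; if `NA`, taken from a `L <int> ...` header line
#'   when present, else from the maximum index seen.
#' @return a [PredictionSet-class].
#' @export
readRR <- function(file, L = NA_integer_) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "\\s+")
  hdr <- vapply(toks, function(t) identical(t[1], "L"), logical(1))
  if (is.na(L) && any(hdr)) L <- as.integer(toks[[which(hdr)[1]]][2])
  rec <- toks[!hdr & vapply(toks, function(t)
    length(t) >= 5 && grepl("^[0-9]+$", t[1]) && grepl("^[0-9]+$", t[2]),
    logical(1))]
  if (length(rec) == 0L) {
    if (is.na(L)) stop("no contact records and no length header in ", file)
    return(predictionSet(L))
  }
  m <- do.call(rbind, lapply(rec, function(t) as.numeric(t[1:5])))
  i <- pmin(m[, 1], m[, 2]); j <- pmax(m[, 1], m[, 2])
  if (is.na(L)) L <- max(j)
  predictionSet(L, i, j, m[, 5])
}

#' Write predictions in CASP RR dialect
#'
#' @param pred a [PredictionSet-class].
#' @param file output path.
#' @param sequence optional one-letter sequence written as a header line.
#' @param dLow,dHigh distance bounds written per record (annotation only).
#' @return `file`, invisibly.
#' @export
writeRR <- function(pred, file, sequence = NULL, dLow = 0, dHigh = 8) {
  it <- predItems(pred)
  lines <- c(if (!is.null(sequence)) sequence,
             sprintf("%d %d %g %g %.6f", it$i, it$j, dLow, dHigh, it$score))
  writeLines(lines, file)
  invisible(file)
}

#' Read a true contact map written by [writeContactMapRR()]
#'
#' @param file path; the first line must be `L <int> KIND <intra|inter>`.
#' @return a [ContactMap-class].
#' @export
readContactMapRR <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (!identical(hdr[1], "L") || !identical(hdr[3], "KIND"))
    stop("missing 'L <int> KIND <intra|inter>' header in ", file)
  L <- as.integer(hdr[2]); kind <- hdr[4]
  if (length(lines) == 1L) return(contactMap(kind, L, NULL))
  m <- do.call(rbind, lapply(strsplit(trimws(lines[-1]), "\\s+"),
                             function(t) as.integer(t[1:2])))
  contactMap(kind, L, m)
}

#' Write a true contact map in RR dialect with a kind header
#'
#' @param map a [ContactMap-class].
#' @param file output path.
#' @param cutoff distance cutoff recorded per line (default 8 for intra,
#'   6 for inter).
#' @return `file`, invisibly.
#' @export
writeContactMapRR <- function(map, file,
                              cutoff = if (contactKind(map) == "intra") 8 else 6) {
  p <- contactPairs(map)
  lines <- c(sprintf("L %d KIND %s", mapLength(map), contactKind(map)),
             if (nrow(p) > 0) sprintf("%d %d 0 %g 1.0", p[, 1], p[, 2], cutoff))
  writeLines(lines, file)
  invisible(file)
}

#' Write a contact map as a dense 0/1 text matrix (debugging aid)
#'
#' @param map a [ContactMap-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeDenseMap <- function(map, file) {
  M <- as.matrix(map) * 1L
  utils::write.table(M, file, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

## ---- PDB and FASTA ------------------------------------------------------

.nucleicResid <- c("A", "C", "G", "U", "I", "N", "T",
                   "DA", "DC", "DG", "DT", "DU", "DI")
.waterResid <- c("HOH", "DOD", "WAT")

#' Read a (possibly multi-chain) PDB file
#'
#' Thin wrapper over `bio3d::read.pdb` that keeps ATOM records only, drops
#' hydrogens/deuterium, waters and nucleic-acid residues, and keeps the first
#' alternate location. The result is the raw material for
#' [splitAndReindex()].
#'
#' @param file path to a PDB file.
#' @return a list of class `RawComplex` with elements `atoms` (data.frame in
#'   file order with columns `chain`, `resno`, `insert`, `resid`, `elety`,
#'   `elesy`, `x`, `y`, `z`) and `sourceId`.
#' @export
readComplexPDB <- function(file) {
  pdb <- bio3d::read.pdb(file, rm.alt = TRUE, verbose = FALSE)
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  a <- a[!(a$resid %in% c(.nucleicResid, .waterResid)), , drop = FALSE]
  elesy <- a$elesy
  miss <- is.na(elesy) | !nzchar(trimws(elesy))
  ## fall back to the first alphabetic character of the atom name
  elesy[miss] <- substr(gsub("[^A-Za-z].*$", "",
                             gsub("^[0-9]+", "", a$elety[miss])), 1, 1)
  a$elesy <- toupper(trimws(elesy))
  a <- a[!(a$elesy %in% c("H", "D")), , drop = FALSE]
  a$insert[is.na(a$insert)] <- ""
  if (nrow(a) == 0L) stop("no protein ATOM records in ", file)
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", file)
  structure(list(atoms = a[, c("chain", "resno", "insert", "resid", "elety",
                               "elesy", "x", "y", "z")],
                 sourceId = basename(file)),
            class = "RawComplex")
}

#' Write one cleaned chain as a single-chain PDB file
#'
#' Emits ATOM records (plus TER and END) through `bio3d::write.pdb`, with
#' three-letter residue names recovered from the one-letter sequence
#' (`X -> UNK`).
#'
#' @param chain a [ChainRecord-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeChainPDB <- function(chain, file) {
  a <- atomTable(chain)
  letters1 <- strsplit(chainSeq(chain), "")[[1]]
  resid3 <- bio3d::aa123(letters1)
  resid3[letters1 == "X"] <- "UNK"
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno,
                   resid = resid3[a$resno],
                   eleno = seq_len(nrow(a)),
                   elety = a$elety,
                   elesy = a$elesy,
                   chain = chainId(chain),
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                   chainter = TRUE, end = TRUE)
  invisible(file)
}

#' Write a multi-chain complex as one PDB file
#'
#' @param chains list of [ChainRecord-class] objects with distinct ids.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeComplexPDB <- function(chains, file) {
  tabs <- lapply(chains, function(ch) {
    a <- atomTable(ch)
    letters1 <- strsplit(chainSeq(ch), "")[[1]]
    r3 <- bio3d::aa123(letters1); r3[letters1 == "X"] <- "UNK"
    a$resid <- r3[a$resno]
    a$chain <- chainId(ch)
    a
  })
  a <- do.call(rbind, tabs)
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   elesy = a$elesy, chain = a$chain,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                   chainter = TRUE, end = TRUE)
  invisible(file)
}

#' Write chain sequences to FASTA
#'
#' @param chains list of [ChainRecord-class] objects.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeChainFasta <- function(chains, file) {
  seqs <- Biostrings::AAStringSet(vapply(chains, chainSeq, character(1)))
  names(seqs) <- vapply(chains, chainId, character(1))
  Biostrings::writeXStringSet(seqs, file)
  invisible(file)
}
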
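# Aligned-sequence container and FASTA I/O.

#' Construct an alignment
#'
#' An alignment is an ordered, id-keyed set of equal-length sequences over
#' the alphabet A, C, G, T, - (gaps). IUPAC ambiguity codes are accepted and
#' treated as uninformative (like gaps) when encoded.
#'
#' @param seqs named character vector of aligned sequences; names are the
#'   record ids.
#' @return an object of class `hp_alignment` with fields `ids`, `seqs`
#'   (named uppercase strings) and `length` (alignment length L).
#' @export
alignment <- function(seqs) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- toupper(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("sequences have unequal lengths: ", paste(range(nchar(seqs)), collapse = " .. "))
  if (L < 1L) stop("alignment length must be >= 1")
  bad <- grepl(sprintf("[^%s]", .ALPHABET_RE), seqs)
  if (any(bad)) {
    s <- seqs[bad][1]
    pos <- regexpr(sprintf("[^%s]", .ALPHABET_RE), s)
    stop(sprintf("illegal character '%s' at position %d of sequence '%s'",
                 substr(s, pos, pos), pos, names(seqs)[bad][1]))
  }
  structure(list(ids = names(seqs), seqs = seqs, length = L),
            class = "hp_alignment")
}

# A, C, G, T, gap, and IUPAC ambiguity codes (encoded uninformatively).
.ALPHABET_RE <- "ACGTNRYSWKMBDHV-"

#' @export
print.hp_alignment <- function(x, ...) {
  cat(sprintf("<hp_alignment> %d sequences of length %d\n",
              length(x$ids), x$length))
  invisible(x)
}

#' @export
length.hp_alignment <- function(x) length(x$ids)

#' Read an aligned FASTA file
#'
#' @param path path to a FASTA file of aligned sequences.
#' @return an [alignment()].
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  # ids are taken up to the first whitespace, matching newick label usage
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  names(seqs) <- ids
  alignment(seqs)
}

#' Write an alignment to FASTA
#'
#' @param aln an [alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "hp_alignment"))
  ss <- Biostrings::BStringSet(aln$seqs)
  names(ss) <- aln$ids
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Subset an alignment by ids
#'
#' @param aln an [alignment()].
#' @param ids character vector of record ids (order preserved).
#' @return the restricted [alignment()].
#' @export
subset_alignment <- function(aln, ids) {
  missing <- setdiff(ids, aln$ids)
  if (length(missing))
    stop("ids not in alignment: ", paste(missing, collapse = ", "))
  alignment(aln$seqs[ids])
}

#' One-hot encode an aligned sequence
#'
#' Encodes a sequence over A, C, G, T, - as a 4 x L matrix with rows in the
#' order A, C, G, T. A, C, G, T columns are standard basis vectors; gaps and
#' ambiguity codes get the uninformative column (1/4, 1/4, 1/4, 1/4), so
#' every column sums to one.
#'
#' @param seq a single aligned sequence (string), case-insensitive.
#' @return a 4 x L numeric matrix with rownames A, C, G, T.
#' @export
encode_one_hot <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- !grepl(sprintf("[%s]", .ALPHABET_RE), chars)
  if (any(bad)) {
    pos <- which(bad)[1]
    stop(sprintf("illegal character '%s' at position %d", chars[pos], pos))
  }
  m <- matrix(0.25, nrow = 4L, ncol = length(chars),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (k in 1:4) {
    hit <- chars == rownames(m)[k]
    m[, hit] <- 0
    m[k, hit] <- 1
  }
  m
}

# One-hot encode a whole alignment into a single 4 x (n*L) matrix with the
# n sequences' columns concatenated in order; the batched layout consumed by
# the encoder network.
.encode_batch <- function(aln, ids = aln$ids) {
  stopifnot(inherits(aln, "hp_alignment"))
  seqs <- aln$seqs[ids]
  L <- aln$length
  chars <- unlist(strsplit(toupper(seqs), "", fixed = TRUE), use.names = FALSE)
  m <- matrix(0.25, nrow = 4L, ncol = length(chars))
  bases <- c("A", "C", "G", "T")
  for (k in 1:4) {
    hit <- chars == bases[k]
    m[, hit] <- 0
    m[k, hit] <- 1
  }
  m
}
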
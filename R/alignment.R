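#' @importFrom stats optim qgamma pgamma qnorm pnorm dnorm lm coef resid
#'   setNames runif rbinom ppois var sd
#' @importFrom utils read.delim write.table packageVersion
NULL

AA_STATES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
NT_STATES <- c("A", "C", "G", "T")

#' Alphabet state set
#'
#' @param alphabet `"aa"` or `"nt"`.
#' @return Character vector of residue states (amino acids in PAML order, or
#'   nucleotides).
#' @export
alphabet_states <- function(alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "aa") AA_STATES else NT_STATES
}

missing_symbols <- function(alphabet) {
  if (alphabet == "aa") c("-", "X", "?", "*", ".") else c("-", "N", "X", "?", ".")
}

#' Construct an alignment object
#'
#' An alignment is a taxa-by-sites character matrix over a nucleotide or
#' amino-acid alphabet plus the gap symbol `-` and an unknown symbol
#' (`X` for amino acids, `N` for nucleotides). Site numbering is 1-based;
#' `positions` records the original alignment column of each site, which is
#' preserved by [extract_sites()].
#'
#' @param mat Character matrix (rows = taxa, must have unique rownames).
#' @param alphabet `"aa"` or `"nt"`; guessed from the residues when `NULL`.
#' @param positions Integer vector of original 1-based column positions.
#' @return An object of class `"aln"`.
#' @export
alignment <- function(mat, alphabet = NULL, positions = NULL) {
  if (!is.matrix(mat) || !is.character(mat)) {
    stop("`mat` must be a character matrix")
  }
  taxa <- rownames(mat)
  if (is.null(taxa) || anyDuplicated(taxa)) {
    stop("taxon names must be present and unique")
  }
  mat[] <- toupper(mat)
  if (is.null(alphabet)) {
    res <- setdiff(unique(as.vector(mat)), c("-", "?", ".", "*"))
    alphabet <- if (all(res %in% c(NT_STATES, "N", "U"))) "nt" else "aa"
  }
  states <- alphabet_states(alphabet)
  mat[mat == "U" & alphabet == "nt"] <- "T"
  unknown <- if (alphabet == "aa") "X" else "N"
  bad <- !(mat %in% c(states, "-", unknown))
  if (any(bad)) mat[bad] <- unknown
  if (is.null(positions)) positions <- seq_len(ncol(mat))
  stopifnot(length(positions) == ncol(mat))
  structure(list(mat = mat, alphabet = alphabet,
                 positions = as.integer(positions)),
            class = "aln")
}

#' @export
print.aln <- function(x, ...) {
  cat(sprintf("<alignment> %d taxa x %d sites (%s)\n",
              nrow(x$mat), ncol(x$mat),
              if (x$alphabet == "aa") "amino acid" else "nucleotide"))
  invisible(x)
}

#' @export
dim.aln <- function(x) dim(x$mat)

aln_taxa <- function(aln) rownames(aln$mat)

#' Read a multiple sequence alignment
#'
#' FASTA parsing is delegated to Biostrings; relaxed sequential PHYLIP and
#' TSV character matrices (taxa in the first column, one column per site or a
#' single sequence column) are parsed directly. Characters are uppercased and
#' unrecognised symbols are mapped to the unknown state.
#'
#' @param path File path.
#' @param format One of `"fasta"`, `"phylip"`, `"tsv-matrix"`.
#' @param alphabet `"aa"`, `"nt"`, or `NULL` to guess.
#' @return An [alignment()] object.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip", "tsv-matrix"),
                           alphabet = NULL) {
  format <- match.arg(format)
  if (format == "fasta") {
    seqs <- Biostrings::readBStringSet(path)
    nm <- sub("\\s.*$", "", names(seqs))
    chars <- strsplit(as.character(seqs), "")
  } else if (format == "phylip") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    hdr <- scan(text = lines[[1]], what = integer(), quiet = TRUE)
    if (length(hdr) != 2) stop("malformed PHYLIP header")
    body <- lines[-1]
    if (length(body) != hdr[[1]]) stop("PHYLIP: wrong number of sequences")
    parts <- regmatches(body, regexpr("^\\S+", body))
    nm <- parts
    chars <- strsplit(gsub("\\s", "", sub("^\\S+", "", body)), "")
  } else {
    df <- read.delim(path, header = TRUE, comment.char = "#",
                     check.names = FALSE, colClasses = "character")
    nm <- df[[1]]
    if (ncol(df) == 2) {
      chars <- strsplit(df[[2]], "")
      pos <- NULL
    } else {
      chars <- lapply(seq_len(nrow(df)), function(i) as.character(df[i, -1]))
      pos <- suppressWarnings(as.integer(colnames(df)[-1]))
      if (anyNA(pos)) pos <- NULL
    }
    lens <- lengths(chars)
    if (length(unique(lens)) != 1) stop("ragged rows in alignment")
    mat <- do.call(rbind, chars)
    rownames(mat) <- nm
    return(alignment(mat, alphabet = alphabet, positions = pos))
  }
  lens <- lengths(chars)
  if (length(unique(lens)) != 1) stop("ragged rows in alignment")
  mat <- do.call(rbind, chars)
  rownames(mat) <- nm
  alignment(mat, alphabet = alphabet)
}

#' Write an alignment to FASTA
#'
#' @param aln An [alignment()].
#' @param path Output path.
#' @export
write_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln$mat))) {
    writeLines(c(paste0(">", rownames(aln$mat)[i]),
                 paste(aln$mat[i, ], collapse = "")), con)
  }
  invisible(path)
}

#' Extract alignment columns
#'
#' Subsets an alignment to the given sites (indices into the current columns),
#' preserving taxon order and the original 1-based `positions` provenance.
#'
#' @param aln An [alignment()].
#' @param sites Integer site indices (must be unique and in range).
#' @return An [alignment()] with `length(sites)` columns.
#' @export
extract_sites <- function(aln, sites) {
  if (length(sites) == 0) stop("cannot extract an empty site set")
  sites <- as.integer(sites)
  if (anyDuplicated(sites)) stop("duplicated sites in extraction")
  if (any(sites < 1 | sites > ncol(aln$mat))) stop("site out of range")
  alignment(aln$mat[, sites, drop = FALSE], alphabet = aln$alphabet,
            positions = aln$positions[sites])
}

# integer encoding: 1..S for states, NA for gap/unknown
encode_alignment <- function(aln) {
  states <- alphabet_states(aln$alphabet)
  enc <- match(aln$mat, states)
  dim(enc) <- dim(aln$mat)
  rownames(enc) <- rownames(aln$mat)
  enc
}

#' Mean pairwise percentage identity
#'
#' Mean over all unordered sequence pairs of the fraction of columns where
#' both sequences are non-gap and identical, among columns where both are
#' non-gap, expressed as a percentage. Pairs with no comparable columns are
#' excluded from the mean.
#'
#' @param aln An [alignment()] with at least two sequences.
#' @return A percentage in `[0, 100]`.
#' @export
mean_pairwise_identity <- function(aln) {
  m <- aln$mat
  n <- nrow(m)
  if (n < 2) stop("need at least two sequences")
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) next
      vals <- c(vals, mean(m[i, ok] == m[j, ok]) * 100)
    }
  }
  if (length(vals) == 0) stop("no comparable sequence pairs")
  mean(vals)
}

#' Translate a codon-oriented nucleotide alignment
#'
#' Translates in frame 1 using the standard genetic code. Codons containing a
#' gap or unknown base translate to `X`; stop codons translate to `X` as well
#' (they carry no residue information for property analyses).
#'
#' @param aln Nucleotide [alignment()] whose length is a multiple of 3.
#' @return An amino-acid [alignment()]; `positions` give the codon index.
#' @export
translate_alignment <- function(aln) {
  if (aln$alphabet != "nt") stop("translation needs a nucleotide alignment")
  L <- ncol(aln$mat)
  if (L %% 3 != 0) stop("alignment length not divisible by 3 (frame error)")
  code <- Biostrings::GENETIC_CODE
  ncod <- L / 3
  out <- matrix("X", nrow(aln$mat), ncod, dimnames = list(rownames(aln$mat), NULL))
  for (k in seq_len(ncod)) {
    cod <- apply(aln$mat[, (3 * k - 2):(3 * k), drop = FALSE], 1, paste, collapse = "")
    aa <- code[cod]
    aa[is.na(aa) | aa == "*"] <- "X"
    out[, k] <- aa
  }
  alignment(out, alphabet = "aa")
}

#' Write a data frame as TSV with a provenance header
#'
#' All tabular outputs carry a `#`-prefixed provenance comment (package
#' version, seed, free-text inputs) so results are traceable.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param inputs Free-text description of the inputs.
#' @param seed Integer seed used (or NA).
#' @export
write_tsv_report <- function(df, path, inputs = "", seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# adaptconv %s | seed=%s | inputs=%s",
                     as.character(packageVersion("adaptconv")),
                     as.character(seed), inputs), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}
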
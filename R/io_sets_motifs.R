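#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Duplicate members within a set are collapsed; empty sets and
#' lines with fewer than three fields are rejected.
#'
#' @param path path to the GMT file.
#' @param top_level optional character vector of set names to flag as
#'   top-level biological-process sets.
#' @return A `GeneSetCollection`: named list of character vectors with
#'   attribute `top_level` (logical vector parallel to the sets).
#' @export
read_gmt <- function(path, top_level = character()) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("malformed GMT line %d: fewer than 3 fields", i))
    members <- unique(fields[-(1:2)])
    members <- members[members != ""]
    if (length(members) == 0L)
      stop(sprintf("GMT line %d: set '%s' has no members", i, fields[[1L]]))
    if (fields[[1L]] %in% names(sets))
      stop("duplicate gene set name: ", fields[[1L]])
    sets[[fields[[1L]]]] <- members
  }
  gene_set_collection(sets, top_level = top_level)
}

#' Construct a validated gene-set collection
#' @param sets named list of character vectors of gene ids.
#' @param top_level character vector of set names flagged top-level.
#' @return `GeneSetCollection` object.
#' @export
gene_set_collection <- function(sets, top_level = character()) {
  if (length(sets) > 0L && (is.null(names(sets)) || any(names(sets) == "")))
    stop("all gene sets must be named")
  dup <- unique(names(sets)[duplicated(names(sets))])
  if (length(dup) > 0L) stop("duplicate set name(s): ", paste(dup, collapse = ", "))
  if (any(lengths(sets) == 0L)) stop("empty gene sets are not allowed")
  unknown <- setdiff(top_level, names(sets))
  if (length(unknown) > 0L)
    stop("top_level names not in collection: ", paste(unknown, collapse = ", "))
  structure(lapply(sets, function(s) unique(as.character(s))),
            top_level = stats::setNames(names(sets) %in% top_level, names(sets)),
            class = "GeneSetCollection")
}

#' Number of top-level sets in a collection
#' @param collection a `GeneSetCollection`.
#' @return integer count of sets flagged top-level.
#' @export
n_top_level <- function(collection) {
  sum(attr(collection, "top_level"))
}

#' Read position frequency matrices in JASPAR raw-count format
#'
#' Accepts both the bracketed dialect (`A [ 8 0 ... ]`) and plain
#' whitespace-separated counts, four rows per motif in A, C, G, T order
#' under a `>name` header.
#'
#' @param path path to the JASPAR PFM text file.
#' @return named list of PFMs, each a 4 x L nonnegative numeric matrix with
#'   rownames `A,C,G,T`.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (length(headers) == 0L) stop("no motif headers ('>') found")
  bounds <- c(headers, length(lines) + 1L)
  pfms <- list()
  for (i in seq_along(headers)) {
    name <- sub("^>\\s*", "", lines[[headers[[i]]]])
    name <- strsplit(trimws(name), "\\s+")[[1L]][[1L]]
    body <- lines[seq(headers[[i]] + 1L, bounds[[i + 1L]] - 1L)]
    if (length(body) != 4L)
      stop(sprintf("motif '%s': expected 4 count rows (A,C,G,T), got %d",
                   name, length(body)))
    rows <- lapply(body, function(ln) {
      ln <- gsub("^[ \t]*[ACGTacgt][ \t]*", "", ln)  # optional base label
      ln <- gsub("[][]", " ", ln)                    # bracket dialect
      vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1L]]))
      if (anyNA(vals)) stop(sprintf("motif '%s': non-numeric count", name))
      vals
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L)
      stop(sprintf("motif '%s': count rows of unequal length (%s)",
                   name, paste(lens, collapse = ", ")))
    mat <- do.call(rbind, rows)
    rownames(mat) <- c("A", "C", "G", "T")
    pfms[[name]] <- validate_pfm(mat, name)
  }
  pfms
}

validate_pfm <- function(mat, name = "motif") {
  if (any(mat < 0)) stop(sprintf("motif '%s': negative count", name))
  if (ncol(mat) < 4L) stop(sprintf("motif '%s': fewer than 4 columns", name))
  if (any(colSums(mat) <= 0)) stop(sprintf("motif '%s': column with zero total", name))
  mat
}

#' Write PFMs in JASPAR raw-count format
#' @param pfms named list of 4 x L count matrices.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jaspar_pfm <- function(pfms, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (name in names(pfms)) {
    writeLines(paste0(">", name), con)
    m <- pfms[[name]]
    for (b in c("A", "C", "G", "T")) {
      writeLines(paste0(b, " [ ", paste(format(m[b, ], trim = TRUE), collapse = " "), " ]"), con)
    }
  }
  invisible(path)
}

#' Read promoter sequences from FASTA keyed by gene id
#'
#' Headers are gene ids (first whitespace-delimited token); one promoter per
#' gene. Lower-case bases are upper-cased; characters outside `A,C,G,T,N`
#' are rejected.
#'
#' @param path path to the FASTA file.
#' @param window optional character note recording the promoter window
#'   definition used (provenance metadata).
#' @return `PromoterSet`: named character vector of upper-case sequences
#'   with attribute `window`.
#' @export
read_fasta_promoters <- function(path, window = NA_character_) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate promoter id(s): ", paste(dup, collapse = ", "))
  txt <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", txt)
  if (any(bad)) {
    offender <- regmatches(txt[bad][[1L]], regexpr("[^ACGTN]", txt[bad][[1L]]))
    stop(sprintf("promoter '%s' contains invalid character '%s'",
                 ids[bad][[1L]], offender))
  }
  promoter_set(stats::setNames(txt, ids), window = window)
}

#' Construct a validated promoter set
#' @param seqs named character vector of sequences over A,C,G,T,N.
#' @param window provenance note (window definition used).
#' @return `PromoterSet` object.
#' @export
promoter_set <- function(seqs, window = NA_character_) {
  if (length(seqs) > 0L && (is.null(names(seqs)) || any(names(seqs) == "")))
    stop("promoters must be named by gene id")
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup) > 0L) stop("duplicate promoter id(s): ", paste(dup, collapse = ", "))
  seqs <- toupper(seqs)
  if (any(grepl("[^ACGTN]", seqs))) stop("promoter sequences restricted to A,C,G,T,N")
  structure(seqs, window = window, class = c("PromoterSet", "character"))
}

#' Write a promoter set as FASTA
#' @param promoters a `PromoterSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_promoters <- function(promoters, path) {
  x <- Biostrings::DNAStringSet(unclass(promoters))
  names(x) <- names(promoters)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
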
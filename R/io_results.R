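#' Write pipeline result tables as TSV with a run-metadata header
#'
#' Each table is written as `<name>.tsv` with stable column order and a
#' comment header recording the seed, package version and config hash, so a
#' result file is self-describing and reruns are comparable.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if missing).
#' @param metadata named list of scalar metadata (e.g. `seed`, `config_hash`);
#'   the package version is added automatically.
#' @return character vector of file paths written, invisibly.
#' @export
write_results <- function(tables, out_dir, metadata = list()) {
  if (length(tables) > 0L && (is.null(names(tables)) || any(names(tables) == "")))
    stop("result tables must be named")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  metadata$version <- as.character(utils::packageVersion("factorex"))
  header <- vapply(names(metadata),
                   function(k) sprintf("# %s: %s", k, as.character(metadata[[k]])),
                   character(1L))
  paths <- character(0L)
  for (name in names(tables)) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    con <- file(path, open = "wt")
    writeLines(header, con)
    suppressWarnings(utils::write.table(tables[[name]], con, sep = "\t",
                                        quote = FALSE, row.names = FALSE,
                                        col.names = TRUE))
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read back a result table written by [write_results()]
#' @param path path to the TSV.
#' @return data.frame (metadata comment lines skipped); the metadata is
#'   attached as attribute `metadata` (named character vector).
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^# ", lines)
  meta_lines <- lines[is_meta & !cumsum(!is_meta)]  # leading comment block only
  meta <- character(0L)
  if (length(meta_lines) > 0L) {
    kv <- regmatches(meta_lines, regexec("^# ([^:]+): (.*)$", meta_lines))
    meta <- stats::setNames(vapply(kv, `[`, character(1L), 3L),
                            vapply(kv, `[`, character(1L), 2L))
  }
  tab <- utils::read.delim(text = paste(lines[!grepl("^# ", lines)], collapse = "\n"),
                           sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  attr(tab, "metadata") <- meta
  tab
}

#' Deterministic hash of a configuration object
#'
#' Serializes the object to canonical text and returns its MD5, used to stamp
#' every output table so results can be traced to the configuration that
#' produced them.
#'
#' @param config any serializable R object (typically a named list).
#' @return 32-character MD5 string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  dump_obj <- function(x, prefix = "") {
    if (is.list(x)) {
      keys <- names(x)
      if (is.null(keys)) keys <- as.character(seq_along(x))
      ord <- order(keys)
      unlist(lapply(ord, function(i)
        dump_obj(x[[i]], paste0(prefix, keys[[i]], "."))))
    } else {
      sprintf("%s=%s", prefix, paste(format(x, digits = 15L), collapse = ","))
    }
  }
  writeLines(dump_obj(config), tmp)
  unname(tools::md5sum(tmp))
}
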
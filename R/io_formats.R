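# Readers/writers for the two-FASTA (AA + lower-case 3Di) convention, the
# whitespace-delimited substitution-matrix format, the metadata TSV and YAML
# run configs.
#
# The 3Di "FASTA dialect" is plain FASTA whose sequences are lower-case
# structure states; AA and 3Di live in separate files joined on record id.

#' Read a FASTA file of amino-acid or 3Di sequences
#'
#' Amino-acid records must be upper case (ambiguous codes B/Z/U/O are mapped to
#' X with a warning); 3Di records must be lower case. Any line wrapping is
#' accepted; order is preserved.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"AA"` or `"3Di"`.
#' @return a tibble with columns `id` and `aa_seq` (or `tdi_seq`).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "ACDEF"), f)
#' read_fasta(f, "AA")
#' @export
read_fasta <- function(path, alphabet = c("AA", "3Di")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0) {
    col <- if (alphabet == "AA") "aa_seq" else "tdi_seq"
    return(tibble::tibble(id = character(), !!col := character()))
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1]) {
    stop(sprintf("FASTA parse error at line 1: expected '>' header, got '%s'",
                 substr(lines[1], 1, 30)), call. = FALSE)
  }
  ids <- sub("^>\\s*", "", lines[is_header])
  ids <- sub("\\s.*$", "", ids)
  if (any(ids == "")) {
    bad_line <- which(is_header)[which(ids == "")[1]]
    stop(sprintf("FASTA parse error at line %d: empty header", bad_line),
         call. = FALSE)
  }
  grp <- cumsum(is_header)
  seqs <- vapply(split(lines[!is_header], grp[!is_header]),
                 paste0, character(1), collapse = "")
  # headers with no sequence lines yield missing groups
  seq_full <- rep("", length(ids))
  seq_full[as.integer(names(seqs))] <- unname(seqs)

  if (alphabet == "AA") {
    n_amb <- sum(vapply(seq_full, function(s)
      sum(split_chars(s) %in% AA_AMBIGUOUS), integer(1)))
    if (n_amb > 0) {
      warning(sprintf("mapped %d ambiguous amino-acid letters (B/Z/U/O) to X",
                      n_amb), call. = FALSE)
      seq_full <- gsub("[BZUO]", "X", seq_full)
    }
  }
  for (i in seq_along(ids)) validate_seq(seq_full[i], alphabet, id = ids[i])
  if (alphabet == "AA") {
    tibble::tibble(id = ids, aa_seq = seq_full)
  } else {
    tibble::tibble(id = ids, tdi_seq = seq_full)
  }
}

#' Write records to FASTA, wrapped at 60 characters
#'
#' @param records tibble with `id` and the sequence column for `alphabet`.
#' @param path output path.
#' @param alphabet `"AA"` or `"3Di"`; selects the `aa_seq` / `tdi_seq` column.
#' @param width line width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, alphabet = c("AA", "3Di"), width = 60) {
  alphabet <- match.arg(alphabet)
  col <- if (alphabet == "AA") "aa_seq" else "tdi_seq"
  if (!col %in% names(records)) stop("records lack column ", col, call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records[[col]][i]
    if (nchar(s) > 0) {
      starts <- seq(1, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
    }
  }
  invisible(path)
}

#' Join amino-acid and 3Di records on id
#'
#' Records whose partner is missing, or whose AA and 3Di lengths disagree, are
#' dropped with a warning reporting the counts.
#'
#' @param aa tibble from [read_fasta()] with `aa_seq`.
#' @param tdi tibble from [read_fasta()] with `tdi_seq`.
#' @return tibble with `id`, `aa_seq`, `tdi_seq`, in the order of `aa`.
#' @export
pair_records <- function(aa, tdi) {
  for (nm in list(list(aa, "aa"), list(tdi, "tdi"))) {
    dup <- nm[[1]]$id[duplicated(nm[[1]]$id)]
    if (length(dup) > 0) {
      stop(sprintf("duplicate id '%s' in %s input", dup[1], nm[[2]]),
           call. = FALSE)
    }
  }
  joined <- dplyr::inner_join(aa[, c("id", "aa_seq")],
                              tdi[, c("id", "tdi_seq")], by = "id")
  n_missing <- nrow(aa) + nrow(tdi) - 2 * nrow(joined)
  mismatch <- nchar(joined$aa_seq) != nchar(joined$tdi_seq)
  if (n_missing > 0) {
    warning(sprintf("%d records dropped for missing partner", n_missing),
            call. = FALSE)
  }
  if (any(mismatch)) {
    warning(sprintf("%d records dropped for AA/3Di length mismatch",
                    sum(mismatch)), call. = FALSE)
  }
  joined[!mismatch, ]
}

#' Read a Foldseek-style substitution matrix file
#'
#' Whitespace-separated square score table with a header row and column of
#' alphabet letters. Letters are matched case-insensitively and stored lower
#' case. With `strict = TRUE` the alphabet must be the 20 3Di letters; with
#' `strict = FALSE` any square symmetric table is accepted (toy fixtures).
#'
#' @param path matrix file.
#' @param gap_open,gap_extend gap penalties (integers, at most 0); a gap run of
#'   length k scores `gap_open + k * gap_extend`.
#' @param strict require the full 20-letter 3Di alphabet.
#' @return a `subst_matrix` object.
#' @export
read_substitution_matrix <- function(path, gap_open = -10L, gap_extend = -1L,
                                     strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(trimws(lines), "\\s+")
  header <- tolower(fields[[1]])
  n <- length(header)
  if (length(fields) != n + 1) {
    stop(sprintf("substitution matrix is not square: %d header letters, %d rows",
                 n, length(fields) - 1), call. = FALSE)
  }
  scores <- matrix(0L, n, n, dimnames = list(header, header))
  for (i in seq_len(n)) {
    row <- fields[[i + 1]]
    if (length(row) != n + 1) {
      stop(sprintf("substitution matrix row %d has %d entries, expected %d",
                   i, length(row) - 1, n), call. = FALSE)
    }
    if (tolower(row[1]) != header[i]) {
      stop(sprintf("row label '%s' does not match header letter '%s'",
                   row[1], header[i]), call. = FALSE)
    }
    scores[i, ] <- as.integer(row[-1])
  }
  subst_matrix(header, scores, gap_open = gap_open, gap_extend = gap_extend,
               strict = strict)
}

#' Write a substitution matrix in the whitespace-delimited square format
#' @param mat a `subst_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_substitution_matrix <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", mat$alphabet), collapse = "  "), con)
  for (i in seq_along(mat$alphabet)) {
    writeLines(paste(c(mat$alphabet[i], format(mat$scores[i, ], width = 3)),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read / write the per-protein metadata TSV
#'
#' Columns: `id`, `plddt`, `cluster_id`, `hierarchy` (dot-separated levels,
#' coarse to fine), `split`.
#' @param path TSV path.
#' @return tibble.
#' @export
read_metadata_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    id = readr::col_character(),
                    plddt = readr::col_double(),
                    cluster_id = readr::col_character(),
                    hierarchy = readr::col_character(),
                    split = readr::col_character()))
}

#' @rdname read_metadata_tsv
#' @param records tibble of protein records.
#' @export
write_metadata_tsv <- function(records, path) {
  cols <- intersect(c("id", "plddt", "cluster_id", "hierarchy", "split"),
                    names(records))
  readr::write_tsv(records[, cols], path)
  invisible(path)
}

#' Attach metadata columns to paired records, joining on id
#' @param records tibble with `id`.
#' @param metadata tibble from [read_metadata_tsv()].
#' @export
join_metadata <- function(records, metadata) {
  dplyr::left_join(records, metadata, by = "id")
}

#' Read / write a YAML run configuration
#' @param path YAML file.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' @rdname read_run_config
#' @param config named list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Structured one-line log messages on stderr.
flog <- function(fmt, ...) {
  message(sprintf("[foldlingo %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}
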
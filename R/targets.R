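#' Build a target list
#'
#' A target list holds the regulated molecules observed in an experiment,
#' each with an optional observed sign of variation: `"+"` (up-regulated),
#' `"-"` (down-regulated) or `"?"` (direction unknown).
#'
#' @param molecule_id Character vector of molecule ids (must be unique).
#' @param sign Observed signs, recycled; `up`/`down`/`unknown` aliases are
#'   accepted.
#' @return A tibble with columns `molecule_id` and `sign`.
#' @export
target_list <- function(molecule_id, sign = "?") {
  molecule_id <- as.character(molecule_id)
  if (anyDuplicated(molecule_id)) {
    abort(paste("duplicated target ids:",
                paste(unique(molecule_id[duplicated(molecule_id)]), collapse = ", ")))
  }
  tibble(molecule_id = molecule_id,
         sign = rep_len(as_sign(sign, "target sign"), length(molecule_id)))
}

#' Read a target list from TSV
#'
#' The format is two tab-separated columns, `molecule_id` and `sign`
#' (`+`, `-` or `?`); a header line is optional and detected by the literal
#' string `molecule_id`. A single-column file is read as all-unknown signs.
#'
#' @param path Path to the TSV file.
#' @return A target-list tibble (see [target_list()]).
#' @export
read_target_list <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(target_list(character()))
  if (grepl("molecule_id", lines[[1]], fixed = TRUE)) lines <- lines[-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  target_list(
    purrr::map_chr(parts, 1),
    purrr::map_chr(parts, function(p) if (length(p) >= 2) p[[2]] else "?")
  )
}

#' Write a target list as TSV
#'
#' @param targets A target-list tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_target_list <- function(targets, path) {
  readr::write_tsv(targets[, c("molecule_id", "sign")], path)
  invisible(path)
}
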
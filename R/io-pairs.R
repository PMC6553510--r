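#' Read a ligand-receptor pair list
#'
#' Two-column TSV (or comma-separated) file of ordered (ligand gene, receptor
#' gene) records. A header row is recognized when both fields of row 1 match
#' the column-name vocabulary "ligand" / "receptor" (any case); otherwise row 1
#' is data. Exact duplicate records are collapsed and the duplicate count is
#' reported via a message. Self-pairs (ligand == receptor) are legal.
#'
#' @param path Path to the pair list.
#' @param provenance Free-text source tag stored as an attribute.
#' @return A `data.frame` with character columns `ligand` and `receptor`,
#'   deduplicated, original order preserved, with attribute `provenance`.
#' @export
#' @examples
#' f <- tempfile(); writeLines(c("Ccl2\tCcr2", "Ccl7\tCcr2", "Ccl2\tCcr2"), f)
#' nrow(read_lr_pairs(f))  # 2 (one duplicate reported)
read_lr_pairs <- function(path, provenance = basename(path)) {
  if (!file.exists(path))
    stop_advcomm("pair list not found: %s", path, class = "advcomm_io_error")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) parse_error(path, 1L, "empty pair list")
  sep <- if (grepl("\t", lines[[1L]])) "\t" else if (grepl(",", lines[[1L]])) "," else "\\s+"
  fields <- strsplit(lines, sep)
  bad <- which(vapply(fields, function(f) sum(nzchar(trimws(f[1:2]))) < 2L ||
                        length(f) < 2L, logical(1)))
  if (length(bad))
    stop_advcomm("%s: rows with missing ligand or receptor field: %s", path,
                 paste(head(bad, 10L), collapse = ", "),
                 class = "advcomm_parse_error")
  lig <- trimws(vapply(fields, `[[`, character(1), 1L))
  rec <- trimws(vapply(fields, `[[`, character(1), 2L))
  if (tolower(lig[[1L]]) %in% c("ligand", "ligand_gene") &&
      tolower(rec[[1L]]) %in% c("receptor", "receptor_gene")) {
    lig <- lig[-1L]; rec <- rec[-1L]
    if (!length(lig)) parse_error(path, 2L, "pair list has a header but no rows")
  }
  dup <- duplicated(paste(lig, rec, sep = "\r"))
  if (any(dup))
    message(sum(dup), " duplicate ligand-receptor record(s) collapsed in ", path)
  pairs <- data.frame(ligand = lig[!dup], receptor = rec[!dup],
                      stringsAsFactors = FALSE)
  attr(pairs, "provenance") <- provenance
  pairs
}

#' Read gene sets in GMT format
#'
#' Each GMT line holds a set name, a description, then the member gene
#' symbols, tab-separated. Set names must be unique; duplicated members within
#' a set are collapsed with a warning.
#'
#' @param path Path to the `.gmt` file.
#' @return A named list of character vectors (one per set), with the
#'   per-set descriptions in attribute `descriptions`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path))
    stop_advcomm("gene set file not found: %s", path, class = "advcomm_io_error")
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) parse_error(path, 1L, "empty GMT file")
  sets <- list(); descs <- character()
  for (ln in keep) {
    f <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      parse_error(path, ln, "GMT line needs name, description and >= 1 member")
    name <- trimws(f[[1L]])
    members <- trimws(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      parse_error(path, ln, "set '%s' has no members", name)
    if (name %in% names(sets))
      parse_error(path, ln, "duplicate set name '%s'", name)
    if (anyDuplicated(members)) {
      warning("set '", name, "' lists ",
              sum(duplicated(members)), " member(s) twice; collapsed",
              call. = FALSE)
      members <- unique(members)
    }
    sets[[name]] <- members
    descs[[name]] <- f[[2L]]
  }
  attr(sets, "descriptions") <- descs
  sets
}
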
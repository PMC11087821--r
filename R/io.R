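#' Read a matrix container from tab-separated text
#'
#' Parses a TSV file whose first row holds column identifiers and whose
#' first column holds row identifiers. Empty cells or `NA` denote missing
#' values and are only legal for `kind = "endpoints"`; the gene-score and
#' association kinds must be complete, and association cells must be 0/1.
#' For `kind = "association"` a JSON sidecar `<path>.json` written by
#' [writeMatrix()] supplies the polarity when present.
#'
#' @param path path to the TSV file.
#' @param kind one of `"endpoints"`, `"genescores"`, `"association"`.
#' @param polarity fallback polarity for association matrices without a
#'   sidecar.
#' @return The corresponding S4 container.
#' @seealso [writeMatrix()]
#' @export
readMatrix <- function(path, kind = c("endpoints", "genescores", "association"),
                       polarity = "side_effects") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) < 2L) stop(sprintf("%s: need a header and at least one row", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  colIds <- header[-1L]
  nCol <- length(colIds)
  body <- fields[-1L]
  rowIds <- vapply(body, `[`, "", 1L)
  ragged <- which(lengths(body) != nCol + 1L)
  if (length(ragged))
    stop(sprintf("%s: ragged row '%s' (%d cells, expected %d)", path,
                 rowIds[ragged[1L]], lengths(body)[ragged[1L]] - 1L, nCol))
  for (ids in list(rowIds, colIds))
    if (anyDuplicated(ids))
      stop(sprintf("%s: duplicated identifier '%s'", path,
                   ids[duplicated(ids)][1L]))
  cells <- vapply(body, function(f) f[-1L], character(nCol))
  cells <- matrix(cells, nrow = nCol)  # vapply returns cols as rows
  vals <- suppressWarnings(matrix(as.numeric(t(cells)),
                                  length(rowIds), nCol,
                                  dimnames = list(rowIds, colIds)))
  missing <- t(cells) == "" | t(cells) == "NA"
  bad <- is.na(vals) & !missing
  if (any(bad))
    stop(sprintf("%s: non-numeric cell in row '%s'", path,
                 rowIds[which(rowSums(bad) > 0)[1L]]))
  if (kind == "endpoints") return(EndpointMatrix(vals, mask = !missing))
  if (any(missing))
    stop(sprintf("%s: missing cell in row '%s' not allowed for kind '%s'",
                 path, rowIds[which(rowSums(missing) > 0)[1L]], kind))
  if (kind == "genescores") return(GeneScoreMatrix(vals))
  offRow <- which(rowSums(!(vals == 0 | vals == 1)) > 0)
  if (length(offRow))
    stop(sprintf("%s: non-binary cell in row '%s'", path, rowIds[offRow[1L]]))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    if (!is.null(meta$polarity)) polarity <- meta$polarity
  }
  AssociationMatrix(vals, polarity = polarity)
}

#' Write a matrix container to tab-separated text
#'
#' Inverse of [readMatrix()]: identifiers in the first row/column, missing
#' endpoint cells written as `NA`, full double precision (round-trips to
#' <= 1e-12 relative error). Association matrices additionally get a JSON
#' sidecar `<path>.json` recording the polarity.
#'
#' @param x an [EndpointMatrix-class], [GeneScoreMatrix-class] or
#'   [AssociationMatrix-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeMatrix <- function(x, path) {
  v <- values(x)
  cells <- matrix(formatC(v, format = "g", digits = 17), nrow(v), ncol(v))
  if (is(x, "EndpointMatrix")) cells[!observedMask(x)] <- "NA"
  if (is(x, "AssociationMatrix"))
    cells <- matrix(formatC(v, format = "d"), nrow(v), ncol(v))
  lines <- c(paste(c("id", colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i)
               paste(c(rownames(v)[i], cells[i, ]), collapse = "\t"), ""))
  writeLines(lines, path)
  if (is(x, "AssociationMatrix"))
    jsonlite::write_json(list(polarity = polarity(x), format = "draphnet-tsv"),
                         paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a target map from two-column TSV
#'
#' Each line holds `target<TAB>drug`; the result maps each target to its set
#' of drug identifiers.
#'
#' @param path path to the TSV (a header line `target\tdrug` is optional).
#' @return Named list: target id -> character vector of drug ids.
#' @export
readTargetMap <- function(path) {
  df <- utils::read.delim(path, header = FALSE, col.names = c("target", "drug"),
                          colClasses = "character")
  if (nrow(df) && identical(tolower(df$target[1L]), "target"))
    df <- df[-1L, , drop = FALSE]
  split(df$drug, df$target)
}

#' Write a target map to two-column TSV
#' @param targets named list: target id -> drug ids.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTargetMap <- function(targets, path) {
  df <- data.frame(target = rep(names(targets), lengths(targets)),
                   drug = unlist(targets, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
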
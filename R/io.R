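#' Write / read a yield cube as long-format CSV
#'
#' The on-disk schema is a plain-text long table with the five named
#' dimension columns `config`, `scenario`, `water`, `year`, `cell`, the value
#' column `yield` and the `valid` mask, preceded by a `# units: t ha-1`
#' header line. Values are serialized with full double precision ("%.17g"),
#' so a write/read round trip is lossless. Reading rejects files with a
#' missing or wrong units attribute and reports any missing dimension column
#' by name.
#'
#' @param cube a [yield_cube()].
#' @param path CSV file path.
#' @return `path` invisibly; for `read_yield_cube`, a `yield_cube`.
#' @export
write_yield_cube <- function(cube, path) {
  dn <- dimnames(cube$values)
  grid <- expand.grid(config = dn$config, scenario = dn$scenario,
                      water = dn$water, year = dn$year, cell = dn$cell,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$yield <- sprintf("%.17g", as.vector(cube$values))
  grid$yield[is.na(as.vector(cube$values))] <- "NA"
  grid$valid <- as.integer(as.vector(cube$mask))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# units: t ha-1", con)
  write.csv(grid, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_yield_cube
#' @export
read_yield_cube <- function(path) {
  first <- readLines(path, n = 1L)
  if (!identical(first, "# units: t ha-1"))
    stop("format error: missing or wrong units attribute (expected 't ha-1')")
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("config", "scenario", "water", "year", "cell")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: missing dimension column(s): ",
         paste(miss, collapse = ", "))
  dn <- lapply(need, function(d) unique(as.character(df[[d]])))
  names(dn) <- need
  dims <- unname(vapply(dn, length, integer(1)))
  vals <- array(NA_real_, dims, dimnames = dn)
  mask <- array(FALSE, dims, dimnames = dn)
  idx <- cbind(match(as.character(df$config), dn$config),
               match(as.character(df$scenario), dn$scenario),
               match(as.character(df$water), dn$water),
               match(as.character(df$year), dn$year),
               match(as.character(df$cell), dn$cell))
  vals[idx] <- as.numeric(df$yield)
  mask[idx] <- df$valid == 1
  yield_cube(vals, mask)
}

#' Write a run manifest
#'
#' JSON record of a pipeline run: seeds, parameters, and every output file
#' with its checksum.
#'
#' @param path manifest path (JSON).
#' @param files character vector of produced files.
#' @param meta named list of run metadata (seed, sizes, version...).
#' @export
write_manifest <- function(path, files, meta = list()) {
  meta$version <- as.character(utils::packageVersion("gridcropens"))
  meta$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  meta$outputs <- lapply(files, function(f)
    list(file = basename(f), md5 = unname(tools::md5sum(f))))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
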
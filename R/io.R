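#' Read a feature x sample count matrix from TSV/CSV
#'
#' First column = feature id, remaining columns = samples. The delimiter is
#' inferred from the file extension (`.csv` = comma, otherwise tab).
#'
#' @param path File path.
#' @return Numeric matrix with feature rownames.
#' @export
read_count_matrix <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "numeric"
  m
}

#' Read sample metadata from TSV/CSV
#'
#' Expects columns `sample`, `group`, `zt`, `replicate` (extra columns kept).
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_metadata <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample", "group", "zt", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Assemble an ASV table from files
#'
#' Reads a count matrix (TSV/CSV, or a BIOM file when the `biomformat`
#' package is installed), a taxonomy table (`feature`, `lineage`) and sample
#' metadata.
#'
#' @param counts_path Count matrix path (TSV/CSV/BIOM).
#' @param taxonomy_path Taxonomy TSV path.
#' @param metadata_path Sample metadata TSV path.
#' @return An `asv_table`.
#' @export
read_asv_table <- function(counts_path, taxonomy_path, metadata_path) {
  if (grepl("\\.biom$", counts_path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM requires the biomformat package")
    b <- biomformat::read_biom(counts_path)
    counts <- as.matrix(biomformat::biom_data(b))
  } else {
    counts <- read_count_matrix(counts_path)
  }
  tax <- utils::read.table(taxonomy_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  meta <- read_metadata(metadata_path)
  new_asv_table(counts, meta, tax)
}

#' Write a matrix or data frame as TSV
#'
#' @param x Matrix (written with a leading `feature` column) or data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  if (is.matrix(x)) x <- data.frame(feature = rownames(x), x,
                                    check.names = FALSE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a long-format calorimetry trace CSV
#'
#' @param trace A `calorimetry_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calorimetry_csv <- function(trace, path) {
  d <- trace$data
  long <- do.call(rbind, lapply(
    c("lux", "vo2", "vco2", "beam_breaks", "food_g", "water_g"),
    function(ch) data.frame(timestamp = d$time_min, animal = trace$animal,
                            channel = ch, value = d[[ch]])))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format calorimetry trace CSV
#'
#' Expects columns `timestamp` (minutes), `animal`, `channel`, `value` with
#' channels `lux`, `vo2`, `vco2`, `beam_breaks`, `food_g`, `water_g`.
#'
#' @param path CSV path.
#' @param body_weight_g Body weight metadata to attach.
#' @return A `calorimetry_trace`.
#' @export
read_calorimetry_csv <- function(path, body_weight_g = NA_real_) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  wide <- stats::reshape(long, idvar = c("timestamp", "animal"),
                         timevar = "channel", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide <- wide[order(wide$timestamp), ]
  cad <- unique(round(diff(wide$timestamp), 6))
  structure(list(
    data = data.frame(time_min = wide$timestamp,
                      zt_h = (wide$timestamp / 60) %% 24,
                      lux = wide$lux, vo2 = wide$vo2, vco2 = wide$vco2,
                      beam_breaks = wide$beam_breaks, food_g = wide$food_g,
                      water_g = wide$water_g),
    cadence_min = if (length(cad) == 1L) cad else NA_real_,
    animal = wide$animal[1L], body_weight_g = body_weight_g,
    truth = NULL
  ), class = "calorimetry_trace")
}
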
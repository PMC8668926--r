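#' Write / read a per-cell table as TSV
#'
#' Column layout: `cell_id`, `genotype`, `tissue`, `cluster`, `axis`,
#' `n_genes`, `mito_frac`, `target_count`, `total_count`, plus
#' `norm_expr` and `class` when present.
#'
#' @param cells Cell table data frame.
#' @param path Output file.
#' @return `path` invisibly (writer) or the data frame (reader).
#' @export
write_cell_table <- function(cells, path) {
  utils::write.table(cells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read contact pairs as 4-column TSV
#'
#' BEDPE-like layout `chrom  posA  chrom  posB` with 1-based positions and
#' no header.
#'
#' @param pairs A [contact_pairs()] object.
#' @param path File path.
#' @param region Region the pairs must fall in (reader only).
#' @return `path` invisibly (writer) or a [contact_pairs()] (reader).
#' @export
write_contact_pairs <- function(pairs, path) {
  stopifnot(inherits(pairs, "contact_pairs"))
  df <- data.frame(chrom_a = pairs$region$chrom,
                   pos_a = as.integer(pairs$pos_a),
                   chrom_b = pairs$region$chrom,
                   pos_b = as.integer(pairs$pos_b))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_pairs
#' @export
read_contact_pairs <- function(path, region) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("expected 4 columns (chrom posA chrom posB)")
  if (!all(df[[1]] == region$chrom) || !all(df[[3]] == region$chrom)) {
    stop("chromosome mismatch with region")
  }
  contact_pairs(region, df[[2]], df[[4]])
}

#' Write / read a contact matrix in triplet text form
#'
#' Upper-triangle triplets `bin_i  bin_j  value` with 0-based bin indices,
#' preceded by comment lines recording the region and bin size.
#'
#' @param m A `contact_matrix`.
#' @param path File path.
#' @return `path` invisibly (writer) or a `contact_matrix` (reader; raw
#'   flags, nothing masked beyond all-zero rows kept as-is).
#' @export
write_matrix_triplet <- function(m, path) {
  stopifnot(inherits(m, "contact_matrix"))
  ut <- which(upper.tri(m$M, diag = TRUE) & m$M != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# region=%s", format(m$region)),
               sprintf("# bin_size=%d", as.integer(m$bin_size))), con)
  writeLines(sprintf("%d\t%d\t%.10g", ut[, 1] - 1L, ut[, 2] - 1L,
                     m$M[ut]), con)
  invisible(path)
}

#' @rdname write_matrix_triplet
#' @export
read_matrix_triplet <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  region <- parse_region(sub("^# region=", "", hdr[1]))
  bin_size <- as.integer(sub("^# bin_size=", "", hdr[2]))
  body <- lines[!startsWith(lines, "#")]
  nb <- n_bins(region, bin_size)
  M <- matrix(0, nb, nb)
  if (length(body)) {
    parts <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    i <- as.integer(parts[, 1]) + 1L
    j <- as.integer(parts[, 2]) + 1L
    v <- as.numeric(parts[, 3])
    M[cbind(i, j)] <- v
    M[cbind(j, i)] <- v
  }
  new_contact_matrix(region, bin_size, M, mask = rep(TRUE, nb))
}

#' Read a generator configuration from YAML or JSON
#'
#' Dispatches on the file extension (`.yaml`/`.yml` via the yaml package,
#' `.json` via jsonlite) and forwards the fields to [cell_sim_config()] or
#' [contact_sim_config()] according to `type`. For contact configs the
#' `region` and anchor fields are `"chrom:start-end"` strings.
#'
#' @param path Config file.
#' @param type `"cells"` or `"contacts"`.
#' @return A `cell_sim_config` or `contact_sim_config`.
#' @export
read_sim_config <- function(path, type = c("cells", "contacts")) {
  type <- match.arg(type)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML configs")
    }
    yaml::read_yaml(path)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("the jsonlite package is required for JSON configs")
    }
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config extension: ", ext)
  }
  if (type == "cells") {
    do.call(cell_sim_config, raw)
  } else {
    raw$region <- parse_region(raw$region)
    if (!is.null(raw$loops)) {
      raw$loops <- lapply(raw$loops, function(lp) {
        list(anchor_a = parse_region(lp$anchor_a),
             anchor_b = parse_region(lp$anchor_b),
             enrichment = lp$enrichment)
      })
    }
    do.call(contact_sim_config, raw)
  }
}
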
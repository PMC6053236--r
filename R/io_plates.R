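# Long-format plate I/O: one well per row, qPCR/TLDA and ddPCR share a schema.

#' Column set of the long-format measurement table
#'
#' Every measurement table handled by mirvar — written, read or generated —
#' uses these columns in this order. qPCR/TLDA rows carry a `ct` value and
#' leave the droplet columns empty; ddPCR rows leave `ct` empty and carry
#' `positives`, `total_droplets` and `droplet_volume_nl`.
#'
#' @return Character vector of column names.
#' @export
measurement_columns <- function() {
  c("experiment_id", "sample_id", "subject_id", "material", "protocol",
    "draw_order", "run_day", "rt_replicate", "pcr_replicate",
    "platform", "assay", "ct", "positives", "total_droplets",
    "droplet_volume_nl")
}

#' Read a long-format measurement table
#'
#' Reads a plate table (CSV or XLSX) of Ct values and droplet counts together
#' with the sample, run and replicate metadata needed downstream. Undetermined
#' Ct wells — the literal cell `"Undetermined"` (ABI export convention) or an
#' empty cell on a qPCR/TLDA row — are represented as `NA` in the `ct`
#' column; `NA` is the explicit undetermined state, never a sentinel number.
#' Determined Ct values above 40 cycles cannot be distinguished from
#' amplification failure and are demoted to undetermined with a warning.
#'
#' @param path Path to the file.
#' @param dialect `"auto"` (default, by file extension), `"csv"` or `"xlsx"`.
#'   XLSX reading requires the readxl package.
#' @return A tibble with the columns of [measurement_columns()], one well per
#'   row, row order preserved.
#' @seealso [write_measurements()]
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' write_measurements(generate_centrifugation_experiment(synthetic_config()), tmp)
#' head(read_measurements(tmp))
#' @export
read_measurements <- function(path, dialect = c("auto", "csv", "xlsx")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "mirvar_io_error")
  }
  if (dialect == "auto") {
    dialect <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  raw <- switch(dialect,
    csv = readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          na = character(), progress = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        abort("reading xlsx requires the 'readxl' package", class = "mirvar_io_error")
      }
      rx <- readxl::read_excel(path, col_types = "text")
      as_tibble(lapply(rx, function(col) ifelse(is.na(col), "", col)))
    }
  )
  parse_measurements(raw)
}

# Validate and type a character table against the documented schema.
parse_measurements <- function(raw) {
  cols <- measurement_columns()
  missing <- setdiff(cols, names(raw))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")),
          class = "mirvar_schema_error")
  }
  raw <- raw[cols]
  blank <- function(x) is.na(x) | trimws(x) == ""
  num <- function(x, what) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!blank(x) & is.na(out))
    if (length(bad) > 0) {
      abort(sprintf("column '%s': non-numeric value '%s' in row %d",
                    what, x[bad[1]], bad[1]), class = "mirvar_validation_error")
    }
    out[blank(x)] <- NA_real_
    out
  }
  int <- function(x, what) {
    out <- num(x, what)
    frac <- which(!is.na(out) & out != round(out))
    if (length(frac) > 0) {
      abort(sprintf("column '%s': non-integer value in row %d", what, frac[1]),
            class = "mirvar_validation_error")
    }
    as.integer(round(out))
  }

  platform <- trimws(raw$platform)
  bad_platform <- which(!platform %in% mirvar_platforms())
  if (length(bad_platform) > 0) {
    abort(sprintf("unknown platform label '%s' in row %d",
                  platform[bad_platform[1]], bad_platform[1]),
          class = "mirvar_validation_error")
  }
  assay <- trimws(raw$assay)
  bad_assay <- which(!assay %in% mirvar_assays())
  if (length(bad_assay) > 0) {
    abort(sprintf("unknown assay label '%s' in row %d",
                  assay[bad_assay[1]], bad_assay[1]),
          class = "mirvar_validation_error")
  }
  material <- trimws(raw$material)
  bad_mat <- which(!blank(material) & !material %in% mirvar_materials())
  if (length(bad_mat) > 0) {
    abort(sprintf("unknown material label '%s' in row %d",
                  material[bad_mat[1]], bad_mat[1]),
          class = "mirvar_validation_error")
  }
  protocol <- trimws(raw$protocol)
  bad_prot <- which(!blank(protocol) & !protocol %in% mirvar_protocols())
  if (length(bad_prot) > 0) {
    abort(sprintf("unknown protocol label '%s' in row %d",
                  protocol[bad_prot[1]], bad_prot[1]),
          class = "mirvar_validation_error")
  }

  ct_chr <- trimws(raw$ct)
  undet <- tolower(ct_chr) == "undetermined"
  ct_chr[undet] <- ""
  ct <- num(ct_chr, "ct")
  over <- which(!is.na(ct) & ct > CT_MAX)
  if (length(over) > 0) {
    warn(sprintf("%d Ct value(s) above %d cycles treated as undetermined",
                 length(over), CT_MAX))
    ct[over] <- NA_real_
  }
  nonpos <- which(!is.na(ct) & ct <= 0)
  if (length(nonpos) > 0) {
    abort(sprintf("column 'ct': non-positive value in row %d", nonpos[1]),
          class = "mirvar_validation_error")
  }

  out <- tibble(
    experiment_id = as.character(raw$experiment_id),
    sample_id = as.character(raw$sample_id),
    subject_id = as.character(raw$subject_id),
    material = material,
    protocol = protocol,
    draw_order = int(raw$draw_order, "draw_order"),
    run_day = int(raw$run_day, "run_day"),
    rt_replicate = int(raw$rt_replicate, "rt_replicate"),
    pcr_replicate = int(raw$pcr_replicate, "pcr_replicate"),
    platform = platform,
    assay = assay,
    ct = ct,
    positives = int(raw$positives, "positives"),
    total_droplets = int(raw$total_droplets, "total_droplets"),
    droplet_volume_nl = num(raw$droplet_volume_nl, "droplet_volume_nl")
  )

  is_dd <- out$platform == "ddPCR"
  out$droplet_volume_nl[is_dd & is.na(out$droplet_volume_nl)] <-
    DEFAULT_DROPLET_VOLUME_NL
  bad_k <- which(is_dd &
                   (is.na(out$positives) | is.na(out$total_droplets) |
                      out$positives < 0 | out$total_droplets < 1 |
                      out$positives > out$total_droplets))
  if (length(bad_k) > 0) {
    i <- bad_k[1]
    abort(sprintf(
      "ddPCR droplet counts invalid in row %d (positives=%s, total_droplets=%s)",
      i, out$positives[i], out$total_droplets[i]),
      class = "mirvar_validation_error")
  }
  out
}

#' Write a long-format measurement table
#'
#' Writes measurements in the documented column order so that
#' `read_measurements()` reproduces the records exactly (numeric fields are
#' serialised at full double precision). Undetermined qPCR/TLDA wells are
#' written as the literal `"Undetermined"`; the empty `ct` field on ddPCR
#' rows stays empty. Only CSV output is supported.
#'
#' @param records Measurement tibble as returned by [read_measurements()] or
#'   the `generate_*` functions.
#' @param path Output path.
#' @param dialect `"csv"` (the only supported output dialect).
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path, dialect = c("csv", "xlsx")) {
  dialect <- match.arg(dialect)
  if (dialect == "xlsx") {
    abort("writing xlsx is not supported; write csv instead",
          class = "mirvar_io_error")
  }
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort("'records' must be a non-empty measurement table",
          class = "mirvar_validation_error")
  }
  missing <- setdiff(measurement_columns(), names(records))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")),
          class = "mirvar_schema_error")
  }
  records <- records[measurement_columns()]
  fmt_dbl <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  fmt_int <- function(x) ifelse(is.na(x), "", as.character(x))
  chr <- tibble(
    experiment_id = as.character(records$experiment_id),
    sample_id = as.character(records$sample_id),
    subject_id = as.character(records$subject_id),
    material = as.character(records$material),
    protocol = as.character(records$protocol),
    draw_order = fmt_int(records$draw_order),
    run_day = fmt_int(records$run_day),
    rt_replicate = fmt_int(records$rt_replicate),
    pcr_replicate = fmt_int(records$pcr_replicate),
    platform = as.character(records$platform),
    assay = as.character(records$assay),
    ct = ifelse(records$platform %in% c("qPCR", "TLDA") & is.na(records$ct),
                "Undetermined", fmt_dbl(records$ct)),
    positives = fmt_int(records$positives),
    total_droplets = fmt_int(records$total_droplets),
    droplet_volume_nl = fmt_dbl(records$droplet_volume_nl)
  )
  readr::write_csv(chr, path, na = "", progress = FALSE)
  invisible(path)
}
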
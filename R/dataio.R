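#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

TREATMENTS <- c("untreated", "vehicle", "kainate")
TIMEPOINTS <- c(1L, 4L, 8L)

#' Condition labels for a sample design
#'
#' Collapses the (treatment, time) design into the four-level condition factor
#' used throughout the splicing analyses: all untreated and vehicle samples are
#' pooled as `"control"`; kainate samples are labelled `"KA1"`, `"KA4"`,
#' `"KA8"` by collection time.
#'
#' @param design A sample-design tibble (see [read_sample_sheet()]).
#' @return Factor of length `nrow(design)` with levels
#'   `control, KA1, KA4, KA8` (unused levels kept for a stable contrast).
#' @export
condition_labels <- function(design) {
  lab <- ifelse(design$treatment == "kainate",
                paste0("KA", design$time_h), "control")
  factor(lab, levels = c("control", "KA1", "KA4", "KA8"))
}

#' Read a sample sheet
#'
#' Reads a TSV with columns `sample_id`, `treatment`, `time_h`, `replicate`
#' and validates the design: treatments are one of untreated/vehicle/kainate
#' (case-insensitive), untreated samples sit at time 0 and treated samples at
#' 1, 4 or 8 h, and sample ids are unique.
#'
#' @param path Path to the TSV file.
#' @return A tibble with one row per sample, treatments normalized to lower
#'   case and `time_h`/`replicate` as integers.
#' @export
read_sample_sheet <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  required <- c("sample_id", "treatment", "time_h", "replicate")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("sample sheet is missing column(s): ", paste(missing, collapse = ", "))
  }
  design <- tibble(
    sample_id = df$sample_id,
    treatment = tolower(trimws(df$treatment)),
    time_h    = suppressWarnings(as.integer(df$time_h)),
    replicate = suppressWarnings(as.integer(df$replicate))
  )
  validate_design(design)
  design
}

validate_design <- function(design) {
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(design$sample_id[duplicated(design$sample_id)]), collapse = ", "))
  }
  bad_trt <- setdiff(unique(design$treatment), TREATMENTS)
  if (length(bad_trt) > 0) {
    stop("unknown treatment token(s): ", paste(bad_trt, collapse = ", "))
  }
  if (anyNA(design$time_h) || anyNA(design$replicate)) {
    stop("non-integer time_h or replicate in sample sheet")
  }
  untr <- design$treatment == "untreated"
  if (any(design$time_h[untr] != 0L)) {
    stop("design error: untreated sample(s) with time_h != 0: ",
         paste(design$sample_id[untr & design$time_h != 0L], collapse = ", "))
  }
  if (any(!design$time_h[!untr] %in% TIMEPOINTS)) {
    stop("design error: treated sample(s) with time_h outside {1,4,8}: ",
         paste(design$sample_id[!untr & !design$time_h %in% TIMEPOINTS],
               collapse = ", "))
  }
  invisible(design)
}

#' Assemble an exon-array dataset
#'
#' Bundles probe annotation, sample design and the probe-by-sample intensity
#' matrix into the container the pipeline operates on. Intensity columns are
#' reordered to match the design's sample order.
#'
#' @param annotation Tibble with columns `probe_id`, `probeset_id`,
#'   `transcript_id`, `probeset_order`, `cross_hybridizing`.
#' @param design Sample-design tibble.
#' @param intensities Numeric matrix, probes in rows (named by `probe_id`),
#'   samples in columns (named by `sample_id`).
#' @param scale `"linear"` or `"log2"`.
#' @return An object of class `exon_dataset`.
#' @export
exon_dataset <- function(annotation, design, intensities, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  annotation <- as_tibble(annotation)
  design <- as_tibble(design)
  if (is.null(colnames(intensities)) || is.null(rownames(intensities))) {
    stop("intensity matrix must carry probe_id rownames and sample_id colnames")
  }
  if (!setequal(colnames(intensities), design$sample_id)) {
    extra <- setdiff(colnames(intensities), design$sample_id)
    miss <- setdiff(design$sample_id, colnames(intensities))
    stop("intensity columns do not match sample sheet",
         if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")),
         if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")))
  }
  if (!identical(rownames(intensities), annotation$probe_id)) {
    stop("intensity rows must match annotation probe_id order")
  }
  intensities <- intensities[, design$sample_id, drop = FALSE]
  structure(
    list(annotation = annotation, design = design,
         intensities = intensities, scale = scale),
    class = "exon_dataset"
  )
}

#' @export
print.exon_dataset <- function(x, ...) {
  cat(sprintf(
    "<exon_dataset> %d probes / %d probesets / %d transcripts x %d samples (%s scale)\n",
    nrow(x$annotation), dplyr::n_distinct(x$annotation$probeset_id),
    dplyr::n_distinct(x$annotation$transcript_id), nrow(x$design), x$scale))
  invisible(x)
}

#' @export
dim.exon_dataset <- function(x) dim(x$intensities)

#' Read a probe-level intensity table
#'
#' Reads a TSV whose first five columns are `probe_id`, `probeset_id`,
#' `transcript_id`, `probeset_order`, `cross_hybridizing` and whose remaining
#' columns are one intensity column per sample. Sample columns are joined with
#' the sample sheet by name and reordered to the sheet's order; unknown or
#' missing sample columns are an error, as are duplicate probe ids and
#' non-numeric intensities.
#'
#' @param path Path to the probe table TSV.
#' @param design Sample-design tibble from [read_sample_sheet()].
#' @param scale Scale of the stored intensities, `"log2"` or `"linear"`.
#' @return An [exon_dataset()].
#' @export
read_probe_table <- function(path, design, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  anno_cols <- c("probe_id", "probeset_id", "transcript_id",
                 "probeset_order", "cross_hybridizing")
  if (length(names(df)) < 5 || !identical(names(df)[1:5], anno_cols)) {
    stop("malformed probe-table header: first five columns must be ",
         paste(anno_cols, collapse = ", "))
  }
  if (anyDuplicated(df$probe_id)) {
    stop("integrity error: duplicated probe_id: ",
         paste(unique(df$probe_id[duplicated(df$probe_id)]), collapse = ", "))
  }
  annotation <- tibble(
    probe_id = df$probe_id,
    probeset_id = df$probeset_id,
    transcript_id = df$transcript_id,
    probeset_order = as.integer(df$probeset_order),
    cross_hybridizing = parse_logical_strict(df$cross_hybridizing)
  )
  sample_cols <- setdiff(names(df), anno_cols)
  mat <- matrix(NA_real_, nrow(df), length(sample_cols),
                dimnames = list(df$probe_id, sample_cols))
  for (s in sample_cols) {
    v <- suppressWarnings(as.numeric(df[[s]]))
    bad <- which(is.na(v) & !is.na(df[[s]]))
    if (anyNA(df[[s]]) ) bad <- union(bad, which(is.na(df[[s]])))
    if (length(bad) > 0) {
      stop(sprintf("parse error: non-numeric intensity at row %d, column '%s'",
                   bad[1], s))
    }
    mat[, s] <- v
  }
  exon_dataset(annotation, design, mat, scale = scale)
}

parse_logical_strict <- function(x) {
  lx <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "t", "1")] <- TRUE
  out[lx %in% c("false", "f", "0")] <- FALSE
  if (anyNA(out)) stop("parse error: non-logical cross_hybridizing value: ",
                       x[which(is.na(out))[1]])
  out
}

#' Validate an exon-array dataset
#'
#' Checks the structural invariants of a dataset and reports every violation
#' without mutating or rejecting the object: negative or missing linear-scale
#' intensities, probesets mapped to more than one transcript, ties in the
#' 5'-to-3' probeset order, and a note when the design deviates from the
#' canonical 4 untreated + 9 vehicle + 9 kainate layout.
#'
#' @param ds An [exon_dataset()].
#' @return A list of class `validation_report` with counts and a tibble of
#'   violations (`code`, `message`); the violations tibble is empty iff all
#'   invariants hold.
#' @export
validate_exon_data <- function(ds) {
  stopifnot(inherits(ds, "exon_dataset"))
  viol <- list()
  add <- function(code, message) {
    viol[[length(viol) + 1L]] <<- tibble(code = code, message = message)
  }
  if (anyNA(ds$intensities)) add("NA_INTENSITY", "missing intensity values present")
  if (ds$scale == "linear" && any(ds$intensities <= 0, na.rm = TRUE)) {
    add("NEG_INTENSITY", "non-positive linear-scale intensity values present")
  }
  multi <- ds$annotation |>
    dplyr::distinct(.data$probeset_id, .data$transcript_id) |>
    dplyr::count(.data$probeset_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi) > 0) {
    add("MULTI_TRANSCRIPT",
        paste0("probeset(s) mapped to >1 transcript: ",
               paste(multi$probeset_id, collapse = ", ")))
  }
  ties <- ds$annotation |>
    dplyr::distinct(.data$transcript_id, .data$probeset_id, .data$probeset_order) |>
    dplyr::count(.data$transcript_id, .data$probeset_order) |>
    dplyr::filter(.data$n > 1)
  if (nrow(ties) > 0) {
    add("ORDER_TIE",
        paste0("tied probeset_order within transcript(s): ",
               paste(unique(ties$transcript_id), collapse = ", ")))
  }
  counts <- ds$design |> dplyr::count(.data$treatment)
  canonical <- setNames(c(9L, 4L, 9L), c("kainate", "untreated", "vehicle"))
  obs <- setNames(rep(0L, 3), names(canonical))
  obs[counts$treatment] <- counts$n
  if (!identical(obs, canonical)) {
    add("NONCANONICAL_DESIGN",
        sprintf("design is %s (canonical: 4 untreated + 9 vehicle + 9 kainate)",
                paste(sprintf("%d %s", obs, names(obs)), collapse = " + ")))
  }
  violations <- if (length(viol)) dplyr::bind_rows(viol) else
    tibble(code = character(), message = character())
  structure(
    list(n_probes = nrow(ds$annotation),
         n_probesets = dplyr::n_distinct(ds$annotation$probeset_id),
         n_transcripts = dplyr::n_distinct(ds$annotation$transcript_id),
         n_samples = nrow(ds$design),
         violations = violations),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d probes, %d probesets, %d transcripts, %d samples\n",
              x$n_probes, x$n_probesets, x$n_transcripts, x$n_samples))
  if (nrow(x$violations) == 0) cat("no violations\n") else print(x$violations)
  invisible(x)
}

#' Write a result table as TSV
#'
#' Writes any result tibble as a plain TSV (UTF-8, '.' decimal separator, no
#' quoting) with numeric fields at full precision, so write-then-read
#' round-trips are lossless at test tolerance.
#'
#' @param tbl A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(tbl, path) {
  out <- as.data.frame(tbl)
  num <- vapply(out, is.numeric, logical(1)) & !vapply(out, is.integer, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.12g", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Write a dataset as probe table + sample sheet
#'
#' Inverse of [read_probe_table()]/[read_sample_sheet()]: exports the dataset's
#' annotation and intensities as a probe-table TSV and its design as a sample
#' sheet, suitable for feeding the pipeline from the command line.
#'
#' @param ds An [exon_dataset()].
#' @param probe_path,sheet_path Output paths.
#' @return A named list of the two paths, invisibly.
#' @export
write_exon_data <- function(ds, probe_path, sheet_path) {
  tbl <- dplyr::bind_cols(ds$annotation, as_tibble(ds$intensities))
  write_result_table(tbl, probe_path)
  write_result_table(ds$design, sheet_path)
  invisible(list(probe_table = probe_path, sample_sheet = sheet_path))
}
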
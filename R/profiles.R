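#' Construct a serum antibody profile matrix
#'
#' Holds per-sample IgG and IgM signals to a panel of glycan array
#' components, together with sample metadata. All downstream thresholding
#' assumes signals are relative fluorescence units on a log base 2 scale;
#' raw linear-scale data must pass through [log2_normalize()] first.
#'
#' @param igg,igm numeric matrices (samples x components) with identical
#'   dimnames; rownames are sample identifiers, colnames component names.
#' @param metadata data.frame with columns `sample_id`,
#'   `recorded_blood_type` (one of A, B, AB, O, unknown) and optionally
#'   `source`; one row per sample. Defaults to all-unknown.
#' @param scale `"log2"` (default) or `"linear"`; linear-scale objects are
#'   refused by the classifiers until normalized.
#' @return an object of class `glycan_profiles`: a list with elements
#'   `igg`, `igm`, `components` (parsed component table) and `metadata`,
#'   with attribute `scale`.
#' @export
glycan_profiles <- function(igg, igm, metadata = NULL, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(igg), is.matrix(igm), is.numeric(igg), is.numeric(igm))
  if (!identical(dim(igg), dim(igm)) ||
      !identical(dimnames(igg), dimnames(igm))) {
    stop("IgG and IgM matrices must have identical dimensions and dimnames")
  }
  if ((nrow(igg) > 0 && is.null(rownames(igg))) || is.null(colnames(igg))) {
    stop("signal matrices need sample rownames and component colnames")
  }
  samples <- if (is.null(rownames(igg))) character(0) else rownames(igg)
  if (anyDuplicated(samples)) {
    stop("duplicate sample identifier(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  comp_keys <- canonical_component_name(colnames(igg))
  if (anyDuplicated(comp_keys)) {
    stop("duplicate component name(s): ",
         paste(unique(comp_keys[duplicated(comp_keys)]), collapse = ", "))
  }
  colnames(igg) <- comp_keys
  colnames(igm) <- comp_keys

  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = samples,
                           recorded_blood_type = rep("unknown", length(samples)),
                           stringsAsFactors = FALSE)
  }
  stopifnot(all(c("sample_id", "recorded_blood_type") %in% names(metadata)))
  if (!all(samples %in% metadata$sample_id)) {
    stop("metadata missing sample(s): ",
         paste(setdiff(samples, metadata$sample_id), collapse = ", "))
  }
  metadata <- metadata[match(samples, metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  bad_bt <- !metadata$recorded_blood_type %in% c("A", "B", "AB", "O", "unknown")
  if (any(bad_bt)) {
    stop("invalid recorded_blood_type for sample(s): ",
         paste(metadata$sample_id[bad_bt], collapse = ", "))
  }

  structure(
    list(igg = igg, igm = igm,
         components = parse_component_names(colnames(igg)),
         metadata = metadata),
    class = "glycan_profiles", scale = scale
  )
}

#' @export
print.glycan_profiles <- function(x, ...) {
  cat(sprintf("glycan_profiles: %d samples x %d components (IgG + IgM, %s scale)\n",
              nrow(x$igg), ncol(x$igg), attr(x, "scale")))
  bt <- table(x$metadata$recorded_blood_type)
  cat("recorded blood types:",
      paste(sprintf("%s=%d", names(bt), bt), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.glycan_profiles <- function(x) dim(x$igg)

sample_ids <- function(x) rownames(x$igg)
component_names <- function(x) colnames(x$igg)

#' Extract a per-sample signal vector for a typing target
#'
#' A target is either a single component or a set of components whose log2
#' signals are averaged arithmetically (averaging happens before banding).
#'
#' @param x a `glycan_profiles` object.
#' @param components character vector of component names (whitespace
#'   variants tolerated).
#' @param isotype `"IgG"` or `"IgM"`.
#' @return named numeric vector over samples.
#' @export
target_signal <- function(x, components, isotype = c("IgG", "IgM")) {
  isotype <- match.arg(isotype)
  stopifnot(inherits(x, "glycan_profiles"))
  keys <- canonical_component_name(components)
  idx <- match(keys, component_names(x))
  if (anyNA(idx)) {
    stop("component(s) not present in profiles: ",
         paste(keys[is.na(idx)], collapse = ", "))
  }
  mat <- if (isotype == "IgG") x$igg else x$igm
  if (length(idx) == 1L) mat[, idx] else rowMeans(mat[, idx, drop = FALSE])
}

#' Log2-transform a linear-scale profile matrix
#'
#' Each raw signal becomes `log2(max(raw, floor))`. The object's scale
#' attribute records the transformation, and attempting to transform an
#' already log2-scaled object is an error (prevents double transformation).
#'
#' @param x a `glycan_profiles` object on the linear scale.
#' @param floor positive detection floor in raw RFU (default 1).
#' @param hook optional function applied to each raw signal matrix before
#'   the log transform (pluggable per-array normalization; identity by
#'   default).
#' @return the transformed `glycan_profiles` object on the log2 scale.
#' @export
log2_normalize <- function(x, floor = 1, hook = identity) {
  stopifnot(inherits(x, "glycan_profiles"), floor > 0)
  if (attr(x, "scale") == "log2") {
    stop("profiles are already on the log2 scale; refusing to transform twice")
  }
  if (any(x$igg < 0) || any(x$igm < 0)) stop("negative raw signal encountered")
  x$igg <- log2(pmax(hook(x$igg), floor))
  x$igm <- log2(pmax(hook(x$igm), floor))
  attr(x, "scale") <- "log2"
  x
}

#' Write a profile matrix to a long-format TSV
#'
#' Columns: `sample_id`, `component`, `isotype`, `signal`. Signals are
#' written with 17 significant digits so a write/read round trip reproduces
#' them to full double precision. A companion metadata TSV is written next
#' to the profiles when `metadata_path` is given.
#'
#' @param x a `glycan_profiles` object.
#' @param path output TSV path.
#' @param metadata_path optional path for the sample metadata TSV.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(x, path, metadata_path = NULL) {
  stopifnot(inherits(x, "glycan_profiles"))
  long <- profiles_to_long(x)
  long$signal <- sprintf("%.17g", long$signal)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path)) {
    utils::write.table(x$metadata, metadata_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

profiles_to_long <- function(x) {
  s <- sample_ids(x); k <- component_names(x)
  data.frame(
    sample_id = rep(rep(s, times = length(k)), 2),
    component = rep(rep(k, each = length(s)), 2),
    isotype = rep(c("IgG", "IgM"), each = length(s) * length(k)),
    signal = c(as.vector(x$igg), as.vector(x$igm)),
    stringsAsFactors = FALSE
  )
}

#' Read a profile matrix from TSV/CSV
#'
#' Long format (default) expects columns `sample_id`, `component`,
#' `isotype`, `signal`; wide format expects a `sample_id` column, an
#' `isotype` column, and one column per component. Rows with missing
#' signals are dropped with a message; samples missing any
#' (component, isotype) cell after that are dropped with a message.
#'
#' @param path profile table path (TSV or CSV; separator sniffed from the
#'   header line).
#' @param format `"long"` or `"wide"`.
#' @param metadata_path optional metadata TSV with columns `sample_id`,
#'   `recorded_blood_type` (and optionally more).
#' @param scale scale of the stored signals, `"log2"` (default) or
#'   `"linear"`.
#' @return a `glycan_profiles` object.
#' @export
read_profiles <- function(path, format = c("long", "wide"),
                          metadata_path = NULL, scale = "log2") {
  format <- match.arg(format)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("no samples: file '", path, "' is empty")
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no samples: file '", path, "' has no data rows")

  if (format == "wide") {
    need <- c("sample_id", "isotype")
    if (!all(need %in% names(df))) {
      stop("malformed header: wide format needs columns ",
           paste(need, collapse = ", "))
    }
    comps <- setdiff(names(df), need)
    df <- stats::reshape(df, direction = "long", varying = comps,
                         v.names = "signal", timevar = "component",
                         times = comps, idvar = c("sample_id", "isotype"))
    rownames(df) <- NULL
    df <- df[, c("sample_id", "component", "isotype", "signal")]
  }
  need <- c("sample_id", "component", "isotype", "signal")
  if (!all(need %in% names(df))) {
    stop("malformed header: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (!is.numeric(df$signal)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$signal))) & !is.na(df$signal))
    stop("non-numeric signal in column 'signal' at data row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (!all(df$isotype %in% c("IgG", "IgM"))) {
    stop("isotype column must contain only IgG/IgM")
  }

  n_na <- sum(is.na(df$signal))
  if (n_na > 0L) {
    message("dropping ", n_na, " row(s) with missing signal")
    df <- df[!is.na(df$signal), , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no samples: all rows dropped")

  dup <- df[duplicated(df[c("sample_id", "component", "isotype")]), ]
  if (nrow(dup) > 0L) {
    stop("duplicate sample ID ", dup$sample_id[1L],
         " (component ", dup$component[1L], ", ", dup$isotype[1L], ")")
  }

  samples <- unique(df$sample_id)
  comps <- unique(canonical_component_name(df$component))
  df$component <- canonical_component_name(df$component)
  mats <- lapply(c("IgG", "IgM"), function(iso) {
    m <- matrix(NA_real_, length(samples), length(comps),
                dimnames = list(samples, comps))
    sub <- df[df$isotype == iso, ]
    m[cbind(match(sub$sample_id, samples), match(sub$component, comps))] <- sub$signal
    m
  })
  incomplete <- is.na(mats[[1]]) | is.na(mats[[2]])
  if (any(incomplete)) {
    bad_samples <- samples[rowSums(incomplete) > 0L]
    message("dropping ", length(bad_samples),
            " sample(s) with incomplete signals: ",
            paste(utils::head(bad_samples, 5L), collapse = ", "))
    keep <- setdiff(samples, bad_samples)
    if (length(keep) == 0L) stop("no samples: every sample incomplete")
    mats <- lapply(mats, function(m) m[keep, , drop = FALSE])
  }

  metadata <- NULL
  if (!is.null(metadata_path)) {
    metadata <- utils::read.table(metadata_path, header = TRUE, sep = "\t",
                                  quote = "", stringsAsFactors = FALSE)
  }
  glycan_profiles(mats[[1]], mats[[2]], metadata = metadata, scale = scale)
}

#' Subset a profile matrix by sample
#'
#' @param x a `glycan_profiles` object.
#' @param samples character vector of sample identifiers to keep.
#' @return a `glycan_profiles` object restricted to `samples`.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "glycan_profiles"), all(samples %in% sample_ids(x)))
  glycan_profiles(x$igg[samples, , drop = FALSE], x$igm[samples, , drop = FALSE],
                  metadata = x$metadata[match(samples, x$metadata$sample_id), ,
                                        drop = FALSE],
                  scale = attr(x, "scale"))
}

#' Stub: importing deposited microarray series
#'
#' Public deposits of serum anti-glycan profiling data (e.g. GEO series)
#' ship per-sample supplementary tables of component-level signals. This
#' package does not download or parse such series; to use one, export each
#' channel to the long TSV layout documented in [read_profiles()]
#' (`sample_id`, `component`, `isotype`, `signal` on the log2 scale) along
#' with a metadata TSV of recorded blood types, then call [read_profiles()].
#'
#' @return Called for its documentation; signals an error if invoked.
#' @export
import_geo_series <- function() {
  stop("not implemented: export the series to the documented long TSV ",
       "layout and use read_profiles(); see ?import_geo_series")
}
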
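# ICU-stay data model: one record per stay holding three aligned vital-sign
# series on an implicit 5-minute grid, plus the length-of-stay target in days.
# Long-format CSV readers/writers mirror the layout of bedside-monitor
# archives (stay id, offset minutes, heart rate, respiration, SaO2).

.CHANNELS <- c("heartrate", "respiration", "sao2")

#' ICU stay record
#'
#' @param stay_id Identifier (coerced to character).
#' @param heartrate,respiration,sao2 Numeric series of equal length on the
#'   implicit grid `offset = (k - 1) * sample_interval` minutes from ICU
#'   admission. `NA` marks a missing 5-minute sample. Units: beats/min,
#'   breaths/min, percent.
#' @param los Length of stay in days (positive).
#' @param diagnosis Admission-diagnosis label (free text or a cohort
#'   abbreviation such as `"HF"`, `"RD"`).
#' @param sample_interval Sampling interval in minutes (default 5).
#' @param n_imputed Count of cells filled by [impute_missing()].
#' @return Object of class `stay_record`.
#' @export
stay_record <- function(stay_id, heartrate, respiration, sao2, los,
                        diagnosis = "unknown", sample_interval = 5,
                        n_imputed = 0L) {
  stay_id <- as.character(stay_id)
  lens <- c(length(heartrate), length(respiration), length(sao2))
  if (length(unique(lens)) != 1L) {
    stop(sprintf("stay %s: channel lengths differ (%s)", stay_id,
                 paste(lens, collapse = "/")), call. = FALSE)
  }
  # los may be NA for prediction-only records (target unknown at the bedside)
  if (!is.numeric(los) || length(los) != 1L || (!is.na(los) && los <= 0)) {
    stop(sprintf("stay %s: los must be a single positive number (days)", stay_id),
         call. = FALSE)
  }
  if (any(sao2 < 0 | sao2 > 100, na.rm = TRUE)) {
    stop(sprintf("stay %s: sao2 outside [0, 100]", stay_id), call. = FALSE)
  }
  if (any(heartrate < 0, na.rm = TRUE) || any(respiration < 0, na.rm = TRUE)) {
    stop(sprintf("stay %s: negative heartrate/respiration", stay_id), call. = FALSE)
  }
  structure(list(stay_id = stay_id, diagnosis = as.character(diagnosis),
                 sample_interval = as.numeric(sample_interval),
                 heartrate = as.numeric(heartrate),
                 respiration = as.numeric(respiration),
                 sao2 = as.numeric(sao2),
                 los = as.numeric(los), n_imputed = as.integer(n_imputed)),
            class = "stay_record")
}

#' @export
print.stay_record <- function(x, ...) {
  cat(sprintf("<stay_record %s>  %s, %d samples @ %g min, LOS %.2f d\n",
              x$stay_id, x$diagnosis, length(x$heartrate),
              x$sample_interval, x$los))
  invisible(x)
}

#' Three-channel matrix view of a stay
#'
#' @param record A [stay_record()].
#' @return Numeric matrix, one row per time step, columns
#'   `heartrate`, `respiration`, `sao2` (this order is fixed throughout).
#' @export
channel_matrix <- function(record) {
  m <- cbind(heartrate = record$heartrate, respiration = record$respiration,
             sao2 = record$sao2)
  m
}

#' Cohort of ICU stays
#'
#' @param records List of [stay_record()]s with unique stay ids.
#' @param provenance Free-form metadata list (source files, or simulation
#'   parameters and seed).
#' @return Object of class `cohort_table`.
#' @export
cohort_table <- function(records, provenance = list()) {
  ids <- vapply(records, function(r) r$stay_id, character(1))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate stay ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  names(records) <- ids
  structure(list(records = records, provenance = provenance),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  los <- vapply(x$records, function(r) r$los, numeric(1))
  cat(sprintf("<cohort_table>  %d stays, median LOS %.2f d\n",
              length(x$records), stats::median(los)))
  invisible(x)
}

#' @export
length.cohort_table <- function(x) length(x$records)

#' True length-of-stay targets of a cohort
#' @param table A [cohort_table()].
#' @return Named numeric vector of LOS in days.
#' @export
cohort_los <- function(table) {
  vapply(table$records, function(r) r$los, numeric(1))
}

#' Restrict a stay to its first hours of monitoring
#'
#' Keeps the samples recorded strictly before the cutoff (`offset <
#' hours * 60` minutes), the half-open real-time window. Stays shorter than
#' the window are returned unchanged: they contribute all their data. The
#' LOS target is never truncated.
#'
#' @param record A [stay_record()].
#' @param hours Positive window length; 3, 6, 12 and 24 h are the
#'   conventional real-time horizons.
#' @return A [stay_record()] with at most `hours * 60 / sample_interval`
#'   samples per channel.
#' @export
extract_window <- function(record, hours) {
  stopifnot(inherits(record, "stay_record"), is.numeric(hours), hours > 0)
  keep <- min(length(record$heartrate), ceiling(hours * 60 / record$sample_interval))
  if (keep < 1L) {
    stop(sprintf("stay %s: no samples before the %g h cutoff", record$stay_id, hours),
         call. = FALSE)
  }
  idx <- seq_len(keep)
  record$heartrate <- record$heartrate[idx]
  record$respiration <- record$respiration[idx]
  record$sao2 <- record$sao2[idx]
  record
}

.fill_forward_back <- function(x) {
  obs <- !is.na(x)
  if (!any(obs)) return(NULL)
  idx <- cumsum(obs)            # last observed position at each point
  filled <- x
  filled[idx > 0] <- x[obs][idx[idx > 0]]
  if (idx[1] == 0) {            # leading gap: back-fill with first observation
    first <- which(obs)[1]
    filled[seq_len(first - 1L)] <- x[first]
  }
  filled
}

#' Fill missing 5-minute samples
#'
#' Forward-fills each channel (last observation carried forward), then
#' back-fills any leading gap with the first observed value. The number of
#' filled cells is accumulated in `n_imputed`.
#'
#' @param record A [stay_record()].
#' @return The record with complete channels.
#' @export
impute_missing <- function(record) {
  stopifnot(inherits(record, "stay_record"))
  filled <- 0L
  for (ch in .CHANNELS) {
    x <- record[[ch]]
    y <- .fill_forward_back(x)
    if (is.null(y)) {
      stop(sprintf("stay %s: channel '%s' has no observed values",
                   record$stay_id, ch), call. = FALSE)
    }
    filled <- filled + sum(is.na(x))
    record[[ch]] <- y
  }
  record$n_imputed <- record$n_imputed + filled
  record
}

#' Per-channel z-score normalizer
#'
#' Fits per-channel mean and standard deviation on a training pool only;
#' the same fitted object is then applied to validation and test data so
#' no test-set statistics leak into the fit. A channel with zero spread
#' gets sd 1 with a warning.
#'
#' @param x For `fit_normalizer`: a list of [stay_record()]s or of
#'   three-column channel matrices, or a [cohort_table()]. For
#'   `apply_normalizer`: a single record or matrix.
#' @param normalizer A fitted normalizer.
#' @param invert If `TRUE`, undo the normalization instead.
#' @return `fit_normalizer`: object of class `vital_normalizer` with
#'   numeric vectors `mean` and `sd` (one entry per channel).
#'   `apply_normalizer`: the input with each channel z-scored.
#' @export
fit_normalizer <- function(x) {
  if (inherits(x, "cohort_table")) x <- x$records
  stopifnot(is.list(x))
  if (length(x) == 0L) stop("cannot fit a normalizer on an empty pool", call. = FALSE)
  mats <- lapply(x, function(r) if (inherits(r, "stay_record")) channel_matrix(r) else as.matrix(r))
  pool <- do.call(rbind, mats)
  mu <- colMeans(pool, na.rm = TRUE)
  sd <- apply(pool, 2, stats::sd, na.rm = TRUE)
  zero <- !is.finite(sd) | sd == 0
  if (any(zero)) {
    warning(sprintf("channel(s) with zero spread, sd set to 1: %s",
                    paste(colnames(pool)[zero], collapse = ", ")), call. = FALSE)
    sd[zero] <- 1
  }
  structure(list(mean = mu, sd = sd), class = "vital_normalizer")
}

#' @rdname fit_normalizer
#' @export
apply_normalizer <- function(x, normalizer, invert = FALSE) {
  stopifnot(inherits(normalizer, "vital_normalizer"))
  f <- function(v, j) {
    if (invert) v * normalizer$sd[j] + normalizer$mean[j]
    else (v - normalizer$mean[j]) / normalizer$sd[j]
  }
  if (inherits(x, "stay_record")) {
    for (j in seq_along(.CHANNELS)) x[[.CHANNELS[j]]] <- f(x[[.CHANNELS[j]]], j)
    return(x)
  }
  m <- as.matrix(x)
  for (j in seq_len(ncol(m))) m[, j] <- f(m[, j], j)
  m
}

#' Read a cohort from long-format vitals and stays tables
#'
#' `vitals_file` must have columns `stay_id, offset_minutes, heartrate,
#' respiration, sao2` (header required, missing cells empty); `stays_file`
#' must have `stay_id, diagnosis, los_days`. Offsets are snapped to the
#' nearest point of the 5-minute grid; duplicates landing on one grid point
#' are averaged; grid points with no observation become `NA` cells.
#'
#' @param vitals_file,stays_file Paths to delimited text files (CSV). If
#'   `stays_file` is `NULL` the cohort is built from the vitals alone with
#'   unknown (`NA`) LOS, for prediction-only use.
#' @param sample_interval Grid spacing in minutes.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(vitals_file, stays_file = NULL, sample_interval = 5) {
  vit <- data.table::fread(vitals_file, colClasses = list(character = "stay_id"))
  stays <- if (is.null(stays_file)) {
    data.table::data.table(stay_id = unique(vit$stay_id), diagnosis = "unknown",
                           los_days = NA_real_)
  } else {
    data.table::fread(stays_file, colClasses = list(character = "stay_id"))
  }
  need_v <- c("stay_id", "offset_minutes", .CHANNELS)
  need_s <- c("stay_id", "diagnosis", "los_days")
  if (!all(need_v %in% names(vit))) {
    stop(sprintf("vitals file lacks column(s): %s",
                 paste(setdiff(need_v, names(vit)), collapse = ", ")), call. = FALSE)
  }
  if (!all(need_s %in% names(stays))) {
    stop(sprintf("stays file lacks column(s): %s",
                 paste(setdiff(need_s, names(stays)), collapse = ", ")), call. = FALSE)
  }
  for (cc in c("offset_minutes", .CHANNELS)) {
    if (!is.numeric(vit[[cc]]) && !all(is.na(vit[[cc]]))) {
      bad <- which(!grepl("^\\s*-?[0-9.eE+-]*\\s*$", as.character(vit[[cc]])))[1]
      stop(sprintf("vitals file: unparseable value in column '%s', row %d",
                   cc, if (is.na(bad)) NA_integer_ else bad), call. = FALSE)
    }
  }
  orphan_v <- setdiff(unique(vit$stay_id), stays$stay_id)
  orphan_s <- setdiff(stays$stay_id, unique(vit$stay_id))
  if (nrow(vit) > 0 && length(orphan_v)) {
    stop(sprintf("stays present in vitals but missing from stays table: %s",
                 paste(orphan_v, collapse = ", ")), call. = FALSE)
  }
  if (nrow(vit) > 0 && length(orphan_s)) {
    stop(sprintf("stays present in stays table but missing from vitals: %s",
                 paste(orphan_s, collapse = ", ")), call. = FALSE)
  }
  if (nrow(vit) == 0L) return(cohort_table(list(),
    provenance = list(vitals_file = vitals_file, stays_file = stays_file)))

  vit$grid <- as.integer(round(vit$offset_minutes / sample_interval))
  records <- vector("list", nrow(stays))
  for (i in seq_len(nrow(stays))) {
    sid <- stays$stay_id[i]
    sub <- vit[vit$stay_id == sid, ]
    sub <- sub[order(sub$grid), ]
    n <- max(sub$grid) + 1L
    ch <- matrix(NA_real_, nrow = n, ncol = 3, dimnames = list(NULL, .CHANNELS))
    for (cc in .CHANNELS) {
      agg <- tapply(sub[[cc]], sub$grid, mean, na.rm = TRUE)  # average duplicates
      agg[is.nan(agg)] <- NA_real_
      ch[as.integer(names(agg)) + 1L, cc] <- agg
    }
    records[[i]] <- stay_record(sid, ch[, 1], ch[, 2], ch[, 3],
                                los = stays$los_days[i],
                                diagnosis = stays$diagnosis[i],
                                sample_interval = sample_interval)
  }
  cohort_table(records,
               provenance = list(vitals_file = vitals_file, stays_file = stays_file))
}

#' Write a cohort to long-format vitals and stays tables
#'
#' Inverse of [read_cohort()]: a write-then-read round trip reproduces the
#' numeric content exactly. Missing cells are written as empty fields.
#'
#' @param table A [cohort_table()].
#' @param vitals_file,stays_file Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(table, vitals_file, stays_file) {
  stopifnot(inherits(table, "cohort_table"))
  vit <- data.table::rbindlist(lapply(table$records, function(r) {
    n <- length(r$heartrate)
    data.table::data.table(stay_id = r$stay_id,
                           offset_minutes = (seq_len(n) - 1) * r$sample_interval,
                           heartrate = r$heartrate, respiration = r$respiration,
                           sao2 = r$sao2)
  }))
  if (nrow(vit) == 0L) {
    vit <- data.table::data.table(stay_id = character(), offset_minutes = numeric(),
                                  heartrate = numeric(), respiration = numeric(),
                                  sao2 = numeric())
  }
  stays <- data.table::rbindlist(lapply(table$records, function(r) {
    data.table::data.table(stay_id = r$stay_id, diagnosis = r$diagnosis,
                           los_days = r$los)
  }))
  if (nrow(stays) == 0L) {
    stays <- data.table::data.table(stay_id = character(), diagnosis = character(),
                                    los_days = numeric())
  }
  data.table::fwrite(vit, vitals_file, na = "")
  data.table::fwrite(stays, stays_file, na = "")
  invisible(c(vitals = vitals_file, stays = stays_file))
}
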
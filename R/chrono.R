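# Radiocarbon calibration and 200-year time binning.
#
# Calibration follows the standard intercept-free probabilistic scheme:
# for each calendar year t the likelihood of the measured age is a
# Gaussian in (c14_age - mu_curve(t)) with variance sigma^2 +
# sigma_curve(t)^2, the curve mean and error being linearly interpolated
# to a 1-year grid; the normalised density is the calibrated posterior.

#' Read a calibration curve in the 3-column `.14c` dialect
#'
#' The standard curve format has lines `cal BP, 14C age BP, curve error`
#' (comma- or whitespace-separated) and `#` comment lines. Files may list
#' calendar ages in either direction; the curve is normalised to strictly
#' ascending cal BP.
#'
#' @param path Path to the curve file.
#' @return Object of class `cal_curve`: a data frame with columns
#'   `cal_bp`, `c14_bp`, `sigma_curve`.
#' @export
read_cal_curve <- function(path) {
  if (!file.exists(path)) {
    stop("calibration curve file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("curve file has no data rows", call. = FALSE)
  rows <- lapply(keep, function(i) {
    fields <- strsplit(trimws(lines[i]), "[,\\s]+")[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("malformed curve row at line %d: '%s'", i, lines[i]),
           call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields[1:3]))
    if (anyNA(vals)) {
      stop(sprintf("non-numeric curve row at line %d: '%s'", i, lines[i]),
           call. = FALSE)
    }
    vals
  })
  m <- do.call(rbind, rows)
  curve <- data.frame(cal_bp = m[, 1L], c14_bp = m[, 2L],
                      sigma_curve = m[, 3L])
  curve <- curve[order(curve$cal_bp), , drop = FALSE]
  rownames(curve) <- NULL
  validate_cal_curve(curve)
}

validate_cal_curve <- function(curve) {
  if (any(curve$sigma_curve <= 0)) {
    stop("calibration curve has non-positive errors", call. = FALSE)
  }
  if (any(diff(curve$cal_bp) <= 0)) {
    stop("calibration curve calendar ages are not strictly monotone",
         call. = FALSE)
  }
  class(curve) <- c("cal_curve", "data.frame")
  curve
}

#' Identity calibration curve for testing and simulation
#'
#' A toy curve with `c14_bp == cal_bp` and constant error, on which
#' calibration reduces to a Gaussian centred at the measured age.
#'
#' @param cal_min,cal_max Calendar range covered (years BP).
#' @param step Knot spacing in years.
#' @param sigma Constant curve error (> 0).
#' @return A `cal_curve` object.
#' @export
identity_cal_curve <- function(cal_min = 5000, cal_max = 10000, step = 5,
                               sigma = 1) {
  grid <- seq(cal_min, cal_max, by = step)
  validate_cal_curve(data.frame(cal_bp = grid, c14_bp = grid,
                                sigma_curve = rep(sigma, length(grid))))
}

#' Write a calibration curve in the `.14c` dialect
#'
#' Rows are written with descending cal BP, the convention of published
#' curve files.
#'
#' @param curve A `cal_curve` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cal_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# cal BP, 14C age BP, curve error (1 sigma)", con)
  ord <- order(curve$cal_bp, decreasing = TRUE)
  writeLines(sprintf("%g,%g,%g", curve$cal_bp[ord], curve$c14_bp[ord],
                     curve$sigma_curve[ord]), con)
  invisible(path)
}

#' Read a radiocarbon date table
#'
#' Expects a CSV `lab_code,site_id,level_id,c14_age,sigma,material_class`;
#' `material_class` is one of `short_lived`, `long_lived`, `aggregate`,
#' `unknown` (missing column defaults to `unknown`).
#'
#' @param path Path to the CSV file.
#' @return Data frame of dates with a `context` column appended.
#' @export
read_c14_dates <- function(path) {
  if (!file.exists(path)) {
    stop("radiocarbon date file not found: ", path, call. = FALSE)
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lab_code", "site_id", "level_id", "c14_age", "sigma")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    stop("date file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(d$material_class)) d$material_class <- "unknown"
  ok <- c("short_lived", "long_lived", "aggregate", "unknown")
  bad <- which(!(d$material_class %in% ok))
  if (length(bad) > 0L) {
    stop(sprintf("unknown material_class '%s' (row %d)",
                 d$material_class[bad[1L]], bad[1L]), call. = FALSE)
  }
  if (any(d$sigma <= 0) || any(d$c14_age <= 0)) {
    stop("dates must have positive c14_age and sigma", call. = FALSE)
  }
  d$context <- paste(d$site_id, d$level_id, sep = ":")
  d
}

#' Filter radiocarbon dates by error and material rules
#'
#' Drops dates whose 1-sigma error exceeds `sd_cutoff` years (strictly
#' greater than; a date at exactly the cutoff is kept) and dates on
#' aggregate samples. One message is emitted per dropped date naming the
#' rule applied.
#'
#' @param dates Data frame of dates (see [read_c14_dates()]).
#' @param sd_cutoff Maximum admissible 1-sigma error in years.
#' @return The kept dates.
#' @export
filter_c14_dates <- function(dates, sd_cutoff = 100) {
  drop_sd <- dates$sigma > sd_cutoff
  drop_ag <- !is.null(dates$material_class) &
    dates$material_class == "aggregate"
  for (i in which(drop_sd)) {
    message(sprintf("dropping %s: error %g > %g years",
                    dates$lab_code[i], dates$sigma[i], sd_cutoff))
  }
  for (i in which(drop_ag & !drop_sd)) {
    message(sprintf("dropping %s: aggregate sample", dates$lab_code[i]))
  }
  kept <- dates[!(drop_sd | drop_ag), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' Calibrate a radiocarbon date
#'
#' Computes the calibrated posterior on a 1-year calendar grid. The
#' likelihood at calendar year t is the Gaussian density of the measured
#' age about the interpolated curve mean with variance
#' `sigma^2 + sigma_curve(t)^2`; the posterior is normalised to sum to 1.
#' The two-sigma set is the highest-posterior-density set accumulated in
#' descending probability order to at least 95.4% mass.
#'
#' @param c14_age Measured radiocarbon age (years BP).
#' @param sigma 1-sigma measurement error (years, > 0).
#' @param curve A `cal_curve` object.
#' @param level Probability mass of the HPD set (default two-sigma, 0.954).
#' @return Object of class `cal_density` with fields `grid` (cal BP,
#'   ascending), `prob` (posterior mass per year), `two_sigma` (logical
#'   HPD membership), `mode`, `median`.
#' @export
calibrate_date <- function(c14_age, sigma, curve, level = 0.954) {
  stopifnot(length(c14_age) == 1L, length(sigma) == 1L, sigma > 0)
  if (c14_age < min(curve$c14_bp) || c14_age > max(curve$c14_bp)) {
    stop(sprintf("date %g BP lies outside the curve's 14C range [%g, %g]",
                 c14_age, min(curve$c14_bp), max(curve$c14_bp)),
         call. = FALSE)
  }
  grid <- seq(ceiling(min(curve$cal_bp)), floor(max(curve$cal_bp)), by = 1)
  mu <- stats::approx(curve$cal_bp, curve$c14_bp, xout = grid)$y
  tau <- stats::approx(curve$cal_bp, curve$sigma_curve, xout = grid)$y
  dens <- stats::dnorm(c14_age, mean = mu, sd = sqrt(sigma^2 + tau^2))
  total <- sum(dens)
  if (!is.finite(total) || total <= 0) {
    stop("calibration produced no posterior mass inside the curve support",
         call. = FALSE)
  }
  prob <- dens / total
  # trim the numerically empty tails, keeping a contiguous window
  nz <- which(prob > 1e-12)
  lo <- min(nz); hi <- max(nz)
  grid <- grid[lo:hi]
  prob <- prob[lo:hi] / sum(prob[lo:hi])
  ord <- order(prob, decreasing = TRUE)
  k <- which(cumsum(prob[ord]) >= level)[1L]
  two_sigma <- logical(length(prob))
  two_sigma[ord[seq_len(k)]] <- TRUE
  cum <- cumsum(prob)
  structure(list(grid = grid, prob = prob, two_sigma = two_sigma,
                 mode = grid[which.max(prob)],
                 median = grid[which(cum >= 0.5)[1L]],
                 c14_age = c14_age, sigma = sigma),
            class = "cal_density")
}

#' @export
print.cal_density <- function(x, ...) {
  rng <- range(x$grid[x$two_sigma])
  cat(sprintf("Calibrated %g +/- %g BP: median %d cal BP, 2-sigma %d-%d cal BP\n",
              x$c14_age, x$sigma, x$median, rng[2L], rng[1L]))
  invisible(x)
}

#' Define contiguous calendar time bins
#'
#' Bins tile `[end, start]` cal BP in contiguous `width`-year intervals
#' with no shared years: bin `"8600-8401"` is the closed calendar-year
#' set 8600..8401 cal BP.
#'
#' @param start Oldest calendar year covered (inclusive, cal BP).
#' @param end Youngest calendar year covered (inclusive, cal BP).
#' @param width Bin width in years.
#' @return Data frame `label,start,end`, oldest bin first.
#' @export
#' @examples
#' time_bins() # the nine 200-year bins spanning 8600-6801 cal BP
time_bins <- function(start = 8600, end = 6801, width = 200) {
  span <- start - end + 1L
  if (span <= 0 || span %% width != 0) {
    stop("bin range [end, start] must be a whole number of bins wide",
         call. = FALSE)
  }
  starts <- seq(start, end + width - 1L, by = -width)
  ends <- starts - width + 1L
  data.frame(label = sprintf("%d-%d", starts, ends),
             start = starts, end = ends, stringsAsFactors = FALSE)
}

# Fraction of a calibrated density's mass inside one bin.
# base "two_sigma": mass restricted to the HPD set and renormalised;
# base "full": raw posterior mass.
bin_mass_fraction <- function(density, bin_start, bin_end,
                              base = c("two_sigma", "full")) {
  base <- match.arg(base)
  inside <- density$grid <= bin_start & density$grid >= bin_end
  if (base == "two_sigma") {
    sel <- density$two_sigma
    sum(density$prob[inside & sel]) / sum(density$prob[sel])
  } else {
    sum(density$prob[inside])
  }
}

#' Assign dated contexts to time bins by probability mass
#'
#' For each date, the fraction of its two-sigma-restricted (renormalised)
#' posterior mass falling inside each bin is computed; a bin enters a
#' context's membership set when the fraction reaches `threshold` for any
#' of the context's dates (`combine = "any"`, the default) or for all of
#' them (`combine = "all"`). A date for which no bin reaches the
#' threshold raises a warning; contexts left without any bin are excluded
#' with a message.
#'
#' @param dates Filtered date table (see [filter_c14_dates()]).
#' @param curve A `cal_curve` object.
#' @param bins Bin table from [time_bins()].
#' @param threshold Minimum probability-mass fraction (default 0.35).
#' @param mass_base `"two_sigma"` (renormalised within the HPD set, the
#'   default) or `"full"` (raw posterior mass).
#' @param combine `"any"` or `"all"` across a context's dates.
#' @return Data frame `site_id,level_id,context,bins` with bin labels
#'   joined by `";"`, one row per context that received at least one bin.
#'   Non-consecutive membership sets raise a warning.
#' @export
assign_time_bins <- function(dates, curve, bins, threshold = 0.35,
                             mass_base = c("two_sigma", "full"),
                             combine = c("any", "all")) {
  mass_base <- match.arg(mass_base)
  combine <- match.arg(combine)
  stopifnot(nrow(dates) > 0L)
  if (is.null(dates$context)) {
    dates$context <- paste(dates$site_id, dates$level_id, sep = ":")
  }
  out <- list()
  for (ctx in unique(dates$context)) {
    dd <- dates[dates$context == ctx, , drop = FALSE]
    hits <- matrix(FALSE, nrow(dd), nrow(bins))
    for (i in seq_len(nrow(dd))) {
      dens <- calibrate_date(dd$c14_age[i], dd$sigma[i], curve)
      frac <- vapply(seq_len(nrow(bins)), function(b) {
        bin_mass_fraction(dens, bins$start[b], bins$end[b], base = mass_base)
      }, numeric(1L))
      hits[i, ] <- frac >= threshold
      if (!any(hits[i, ])) {
        warning(sprintf("date %s (%s) reaches no bin at threshold %.2f",
                        dd$lab_code[i], ctx, threshold), call. = FALSE)
      }
    }
    member <- if (combine == "any") apply(hits, 2L, any)
              else apply(hits, 2L, all)
    idx <- which(member)
    if (length(idx) == 0L) {
      message(sprintf("context %s excluded: no bin reaches %.0f%% mass",
                      ctx, 100 * threshold))
      next
    }
    if (length(idx) > 1L && any(diff(idx) != 1L)) {
      warning(sprintf("context %s has non-consecutive bin memberships (%s)",
                      ctx, paste(bins$label[idx], collapse = ";")),
              call. = FALSE)
    }
    out[[ctx]] <- data.frame(site_id = dd$site_id[1L],
                             level_id = dd$level_id[1L],
                             context = ctx,
                             bins = paste(bins$label[idx], collapse = ";"),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map printed time frames to bin memberships
#'
#' Published assemblage tables often report each context's occupation as
#' a calendar time frame (e.g. `"8400-8001"`) rather than per-date
#' posteriors. This helper assigns a context to every bin its frame
#' overlaps by at least `min_overlap` years (default half a 200-year
#' bin), which absorbs frames whose printed endpoints are one year off
#' the bin grid.
#'
#' @param frames Character vector of `"start-end"` time frames (cal BP).
#' @param bins Bin table from [time_bins()].
#' @param min_overlap Minimum overlap in calendar years for membership.
#' @return List of character vectors of bin labels, one per frame.
#' @export
frames_to_bins <- function(frames, bins, min_overlap = 100) {
  parts <- strsplit(frames, "-", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed time frame '%s'", frames[bad[1L]]), call. = FALSE)
  }
  lapply(parts, function(p) {
    fs <- as.numeric(p[1L]); fe <- as.numeric(p[2L])
    if (is.na(fs) || is.na(fe) || fs < fe) {
      stop(sprintf("malformed time frame '%s-%s'", p[1L], p[2L]),
           call. = FALSE)
    }
    ov <- pmax(0, pmin(fs, bins$start) - pmax(fe, bins$end) + 1)
    bins$label[ov >= min_overlap]
  })
}
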
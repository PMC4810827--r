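# Before/after comparison of fitted ERGMs across a regime shift.

#' Reference ERGM estimates for the Baltic Sea food webs
#'
#' The bundled table of published ERGM parameter estimates for four Baltic
#' Sea food webs - offshore and coastal (Aland Islands) regions, each
#' before (1980s) and after (2000s) the reported late-1980s regime shift -
#' under the seven-configuration model (arc baseline, generalist, highly
#' predated species, keystone species, omnivory, tri-trophic chain,
#' apparent competition; exploitative competition enters the coastal 2000s
#' model only). \code{sig_*} columns flag configurations whose estimate
#' exceeded twice its standard error.
#'
#' @param column optionally return a single web's estimates as a named
#'   vector (one of \code{"offshore_1980s"}, \code{"offshore_2000s"},
#'   \code{"coast_1980s"}, \code{"coast_2000s"}), with \code{NA} rows
#'   dropped; by default the full data.frame.
#' @return data.frame or named numeric vector.
#' @examples
#' b <- baltic_estimates("coast_1980s")
#' a <- baltic_estimates("coast_2000s")
#' compare_fits(b, a)$table
#' @export
baltic_estimates <- function(column = NULL) {
  tab <- utils::read.csv(system.file("extdata", "baltic_table2.csv",
                                     package = "foodwebERGM", mustWork = TRUE),
                         stringsAsFactors = FALSE)
  if (is.null(column)) return(tab)
  if (!column %in% names(tab)[2:5]) {
    stop(sprintf("unknown web column '%s'", column), call. = FALSE)
  }
  v <- stats::setNames(tab[[column]], tab$configuration)
  v[!is.na(v)]
}

#' Compare two fitted ERGMs across a regime shift
#'
#' For every configuration shared by the two fits, reports the percentage
#' change of the parameter estimate from the earlier to the later period,
#' \code{100 (theta_after - theta_before) / |theta_before|} (undefined and
#' flagged when \code{theta_before = 0}), together with sign-flip and
#' joint-significance flags. Configurations present in only one model are
#' listed separately, never dropped. Fits from different systems (regions)
#' are refused by default: parameter estimates are only comparable within a
#' system.
#'
#' @param before,after \code{ergm_fit} objects (or named numeric vectors of
#'   estimates, for comparisons of published tables; standard errors are
#'   then unavailable).
#' @param allow_cross_system set \code{TRUE} to override the same-region
#'   check.
#' @return object of class \code{"regime_comparison"}: list with
#'   \code{table} (configuration, theta_before, theta_after, se_before,
#'   se_after, pct_change, sign_flip, both_significant), \code{unshared}
#'   (data.frame of one-sided configurations and which fit has them).
#' @examples
#' cmp <- compare_fits(c(arc = -1, tri_trophic = -0.3501),
#'                     c(arc = -1, tri_trophic = -0.4182))
#' cmp$table  # tri-trophic decreased by 19.45%
#' @export
compare_fits <- function(before, after, allow_cross_system = FALSE) {
  b <- as_fit_summary(before)
  a <- as_fit_summary(after)
  if (!allow_cross_system &&
      !is.null(b$region) && !is.null(a$region) &&
      !identical(b$region, a$region)) {
    stop(sprintf(paste0(
      "fits come from different systems ('%s' vs '%s'); offshore and coastal ",
      "webs are compared separately - set allow_cross_system = TRUE to force"),
      b$region, a$region), call. = FALSE)
  }
  shared <- intersect(names(b$theta), names(a$theta))
  if (!length(shared)) stop("the fits share no configuration", call. = FALSE)
  tb <- b$theta[shared]
  ta <- a$theta[shared]
  pct <- ifelse(tb != 0, 100 * (ta - tb) / abs(tb), NA_real_)
  tab <- data.frame(
    configuration = shared,
    theta_before = as.numeric(tb),
    theta_after = as.numeric(ta),
    se_before = as.numeric(b$se[shared]),
    se_after = as.numeric(a$se[shared]),
    pct_change = as.numeric(pct),
    sign_flip = sign(tb) * sign(ta) < 0,
    both_significant = as.logical(b$sig[shared] & a$sig[shared]),
    stringsAsFactors = FALSE
  )
  only_b <- setdiff(names(b$theta), shared)
  only_a <- setdiff(names(a$theta), shared)
  unshared <- data.frame(
    configuration = c(only_b, only_a),
    present_in = rep(c("before", "after"), c(length(only_b), length(only_a))),
    theta = as.numeric(c(b$theta[only_b], a$theta[only_a])),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, unshared = unshared), class = "regime_comparison")
}

# accept ergm_fit or bare named numeric estimates
as_fit_summary <- function(x) {
  if (inherits(x, "ergm_fit")) {
    list(theta = x$theta, se = x$standard_errors, sig = x$significant,
         region = x$web_metadata$region)
  } else if (is.numeric(x) && !is.null(names(x))) {
    list(theta = x,
         se = stats::setNames(rep(NA_real_, length(x)), names(x)),
         sig = stats::setNames(rep(NA, length(x)), names(x)),
         region = NULL)
  } else {
    stop("expected an ergm_fit or a named numeric vector", call. = FALSE)
  }
}

#' @export
print.regime_comparison <- function(x, ...) {
  cat("<regime_comparison>\n")
  print(x$table, row.names = FALSE, digits = 4)
  if (nrow(x$unshared)) {
    cat("configurations in only one model:\n")
    print(x$unshared, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Write a regime comparison to CSV
#' @param comparison a \code{regime_comparison}.
#' @param path destination CSV.
#' @return \code{path}, invisibly.
#' @export
write_comparison_csv <- function(comparison, path) {
  tab <- comparison$table
  if (nrow(comparison$unshared)) {
    extra <- comparison$unshared
    pad <- tab[0, ]
    for (k in seq_len(nrow(extra))) {
      row <- tab[NA_integer_, ]
      row$configuration <- extra$configuration[k]
      if (extra$present_in[k] == "before") row$theta_before <- extra$theta[k]
      else row$theta_after <- extra$theta[k]
      pad <- rbind(pad, row)
    }
    tab <- rbind(tab, pad)
  }
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
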
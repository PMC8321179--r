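## Experiment harness: run every daltonisation method over a grid of
## observers and images, collect GPF and PSNR, and compare the isotropic
## and anisotropic variants with a paired Wilcoxon test.

#' Default observer grid
#'
#' The four simulated observers used by [evaluate_daltonisation()]:
#' red-green and blue-yellow, each as a dichromat (`alpha = 1`) and a
#' strong anomalous trichromat (`alpha = 0.8`).
#'
#' @return list of [cvd_observer()] objects.
#' @export
default_observer_grid <- function() {
  list(cvd_observer("rg", 1.0), cvd_observer("rg", 0.8),
       cvd_observer("by", 1.0), cvd_observer("by", 0.8))
}

#' Run the daltonisation evaluation grid
#'
#' Daltonises every image with every method for every observer, measuring
#' per run the gamut pixel fraction of the output and its PSNR against the
#' original.  The summary reports per-method medians and the paired
#' two-sided Wilcoxon signed-rank comparison of the isotropic and
#' anisotropic methods (pairs = image x observer runs) for both metrics.
#' The whole grid is deterministic given the input images and
#' configuration.
#'
#' @param images list of `H x W x 3` arrays (e.g. from [fixture_suite()]);
#'   unnamed lists are named `img01`, `img02`, ...
#' @param observers list of [cvd_observer()]s
#'   (default [default_observer_grid()]).
#' @param methods subset of `c("simple", "isotropic", "anisotropic")`.
#' @param cfg a [solver_config()].
#' @param grey_axis passed to [daltonise()].
#' @param out_dir if non-`NULL`, every daltonised image and its simulation
#'   for the corresponding observer are written there as PNG
#'   (`<image>_<kind><alpha>_<method>[_sim].png`).
#' @param verbose print a one-line summary per run.
#' @return object of class `"daltonisation_report"`: list with
#'   `results` (data frame: image, kind, alpha, method, iterations, gpf,
#'   psnr_db), `summary` (data frame of per-method medians, plus a row for
#'   the originals' GPF) and `wilcoxon` (data frame: metric, p_value,
#'   median_isotropic, median_anisotropic; `NULL` unless both diffusion
#'   methods were run).
#' @export
evaluate_daltonisation <- function(images,
                                   observers = default_observer_grid(),
                                   methods = c("simple", "isotropic",
                                               "anisotropic"),
                                   cfg = solver_config(),
                                   grey_axis = c("flat", "luminance"),
                                   out_dir = NULL, verbose = FALSE) {
  if (length(images) == 0L) stop("no images supplied")
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(methods) == 0L) stop("empty method set")
  if (length(observers) == 0L) stop("empty observer grid")
  for (o in observers) stopifnot(inherits(o, "cvd_observer"))
  grey_axis <- match.arg(grey_axis)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (is.null(names(images)))
    names(images) <- sprintf("img%02d", seq_along(images))

  rows <- list()
  n_fail <- 0L
  for (iname in names(images)) {
    u0 <- images[[iname]]
    for (obs in observers) {
      for (method in methods) {
        row <- tryCatch({
          out <- daltonise(u0, obs, method = method, cfg = cfg,
                           grey_axis = grey_axis)
          diag <- attr(out, "diagnostics")
          if (!is.null(out_dir)) {
            tag <- sprintf("%s_%s%g_%s", iname, obs$kind, obs$alpha, method)
            write_image(out, file.path(out_dir, paste0(tag, ".png")))
            write_image(simulate_cvd(out, obs),
                        file.path(out_dir, paste0(tag, "_sim.png")))
          }
          data.frame(image = iname, kind = obs$kind, alpha = obs$alpha,
                     method = method, iterations = diag$iterations,
                     gpf = gamut_pixel_fraction(out),
                     psnr_db = psnr(out, u0))
        }, error = function(e) {
          warning(sprintf("run failed (%s, %s %g, %s): %s", iname,
                          obs$kind, obs$alpha, method, conditionMessage(e)),
                  call. = FALSE)
          n_fail <<- n_fail + 1L
          data.frame(image = iname, kind = obs$kind, alpha = obs$alpha,
                     method = method, iterations = NA_integer_,
                     gpf = NA_real_, psnr_db = NA_real_)
        })
        if (verbose)
          message(sprintf("%s %s a=%g %-11s iter=%4s gpf=%.4f psnr=%.2f",
                          iname, obs$kind, obs$alpha, method,
                          row$iterations, row$gpf, row$psnr_db))
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  results <- do.call(rbind, rows)
  if (all(is.na(results$gpf))) stop("all evaluation runs failed")

  gpf_orig <- vapply(images, gamut_pixel_fraction, numeric(1))
  med <- function(x) stats::median(x, na.rm = TRUE)
  summary_df <- rbind(
    data.frame(method = "original", median_gpf = med(gpf_orig),
               median_psnr_db = Inf),
    do.call(rbind, lapply(methods, function(m) {
      r <- results[results$method == m, ]
      data.frame(method = m, median_gpf = med(r$gpf),
                 median_psnr_db = med(r$psnr_db))
    })))

  wilcoxon <- NULL
  if (all(c("isotropic", "anisotropic") %in% methods)) {
    iso <- results[results$method == "isotropic", ]
    ani <- results[results$method == "anisotropic", ]
    key <- function(r) paste(r$image, r$kind, r$alpha)
    ani <- ani[match(key(iso), key(ani)), ]
    ok <- stats::complete.cases(iso$gpf, ani$gpf)
    cmp <- function(a, b) tryCatch(paired_comparison(a, b),
                                   error = function(e) NULL)
    w_gpf <- cmp(iso$gpf[ok], ani$gpf[ok])
    w_psnr <- cmp(iso$psnr_db[ok], ani$psnr_db[ok])
    wrow <- function(metric, w) if (is.null(w)) NULL else
      data.frame(metric = metric, p_value = w$p_value,
                 median_isotropic = w$median_a,
                 median_anisotropic = w$median_b, n_pairs = w$n_pairs)
    wilcoxon <- rbind(wrow("gpf", w_gpf), wrow("psnr_db", w_psnr))
  }

  structure(list(results = results, summary = summary_df,
                 wilcoxon = wilcoxon, n_failed = n_fail),
            class = "daltonisation_report")
}

#' @export
print.daltonisation_report <- function(x, ...) {
  cat(sprintf("<daltonisation_report> %d runs (%d failed)\n",
              nrow(x$results), x$n_failed))
  cat("\nPer-method medians:\n")
  print(x$summary, row.names = FALSE, digits = 4)
  if (!is.null(x$wilcoxon)) {
    cat("\nPaired Wilcoxon, isotropic vs anisotropic:\n")
    print(x$wilcoxon, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Write a report's tables as CSV
#'
#' @param report a [evaluate_daltonisation()] result.
#' @param dir output directory (created if needed); writes `results.csv`,
#'   `summary.csv` and, when present, `wilcoxon.csv`.
#' @return `dir`, invisibly.
#' @export
write_report_csv <- function(report, dir) {
  stopifnot(inherits(report, "daltonisation_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$results, file.path(dir, "results.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  if (!is.null(report$wilcoxon))
    utils::write.csv(report$wilcoxon, file.path(dir, "wilcoxon.csv"),
                     row.names = FALSE)
  invisible(dir)
}
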
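#' Write study reports (CSV + JSON + figures)
#'
#' Emits machine-readable tables and scatter plots for a study result:
#' `records.csv` (one row per condition per backend, with keypoint, match,
#' index, SSIM and PSNR columns), `correlations.csv`, `stability.csv` (for
#' robustness studies), the full result as `study.json`, and per-series
#' index-vs-SSIM and PSNR-vs-SSIM scatter plots as PNG. Output is
#' deterministic: identical results produce byte-identical CSV/JSON files.
#'
#' @param result a `study_result`.
#' @param out_dir output directory, created if needed.
#' @param plots also render the scatter plots (requires no display).
#' @return character vector of the files written, invisibly.
#' @export
write_report <- function(result, out_dir, plots = TRUE) {
  stopifnot(inherits(result, "study_result"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create `", out_dir, "`")
  }
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(format_num_df(df), path, row.names = FALSE, quote = TRUE)
    path
  }
  files <- c(files, wr(result$records, "records.csv"))
  files <- c(files, wr(result$correlations, "correlations.csv"))
  if (!is.null(result$stability)) {
    files <- c(files, wr(result$stability, "stability.csv"))
  }
  json_path <- file.path(out_dir, "study.json")
  jsonlite::write_json(unclass(result), json_path, digits = NA,
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       dataframe = "columns", na = "null")
  files <- c(files, json_path)
  if (plots) files <- c(files, plot_report(result, out_dir))
  invisible(files)
}

# full-precision, locale-independent numeric formatting for the CSVs
format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      df[[j]] <- formatC(df[[j]], digits = 17, format = "g")
    }
  }
  df
}

plot_report <- function(result, out_dir) {
  files <- character(0)
  recs <- result$records[!is.na(result$records$pi), ]
  for (s in unique(recs$series)) {
    rs <- recs[recs$series == s, ]
    p <- ggplot2::ggplot(rs, ggplot2::aes(x = ssim, y = pi, color = backend,
                                          shape = backend)) +
      ggplot2::geom_point(size = 2) +
      ggplot2::labs(x = "SSIM", y = "mean Hamming distance [bits]",
                    title = sprintf("Keypoint index vs SSIM (%s series)", s)) +
      ggplot2::theme_minimal()
    f <- file.path(out_dir, sprintf("pi_vs_ssim_%s.png", s))
    ggplot2::ggsave(f, p, width = 6, height = 4.5, dpi = 120)
    files <- c(files, f)
    r1 <- rs[!duplicated(rs$label), ]
    p2 <- ggplot2::ggplot(r1, ggplot2::aes(x = ssim, y = psnr)) +
      ggplot2::geom_point(size = 2, color = "grey30") +
      ggplot2::labs(x = "SSIM", y = "PSNR [dB]",
                    title = sprintf("PSNR vs SSIM (%s series)", s)) +
      ggplot2::theme_minimal()
    f2 <- file.path(out_dir, sprintf("psnr_vs_ssim_%s.png", s))
    ggplot2::ggsave(f2, p2, width = 6, height = 4.5, dpi = 120)
    files <- c(files, f2)
  }
  files
}

#' Read a study result back from its JSON report
#'
#' Inverse of the JSON part of [write_report()]: `read_study_result()` of a
#' written report equals the original `study_result`.
#'
#' @param path path to a `study.json` written by [write_report()].
#' @export
read_study_result <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  study_result(as.data.frame(x$records),
               as.data.frame(x$correlations),
               if (is.null(x$stability)) NULL else as.data.frame(x$stability),
               x$params)
}
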
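#' Regression report table (coefficient grid)
#'
#' Renders a collection of [com_gravfit()] fits as the conventional
#' coefficient-(SE) grid: one column per fit, rows for the gravity-level
#' effect, the task effect and the constant, followed by the number of
#' observations, R^2, adjusted R^2, residual standard error and the F
#' statistic. Significance stars follow a configurable legend; the default
#' legend reproduces the reported convention (`*** p < 0.1`, `** p < 0.05`) —
#' because its thresholds are nested the triple star wins whenever p < 0.1,
#' so exact p-values should always be read from the fits themselves, via
#' `summary()`.
#'
#' @param fits named list of `com_gravfit` objects (or `NULL` entries, rendered
#'   as `NA` columns); names become column headers.
#' @param star_legend named numeric vector, names are star strings and values
#'   p thresholds, checked in order (first threshold exceeding p wins).
#' @param digits decimals used for coefficients and SEs.
#' @return Character matrix of class `com_report` (printed as aligned text).
#' @export
#' @examples
#' d <- data.frame(dY = rnorm(12) + rep(c(0, 5), each = 6),
#'                 g_level = rep(c(0, 1), each = 6),
#'                 task_dynamic = rep(c(0, 1), 6))
#' table3_report(list(male_dY = com_gravfit(d, "dY")))
table3_report <- function(fits, star_legend = c("***" = 0.1, "**" = 0.05),
                          digits = 2) {
  if (length(fits) == 0L) {
    out <- matrix(character(0), nrow = 8, ncol = 0)
    rownames(out) <- report_row_names()
    class(out) <- c("com_report", class(out))
    return(out)
  }
  if (is.null(names(fits))) names(fits) <- paste0("fit", seq_along(fits))
  cols <- lapply(fits, function(f) {
    if (is.null(f)) return(rep("NA", 8L))
    cell <- function(term) {
      if (!term %in% names(f$coefficients)) return("NA")
      sprintf("%.*f%s (%.*f)", digits, f$coefficients[term],
              stars_for(f$p.value[term], star_legend), digits, f$se[term])
    }
    fs <- f$fstatistic
    c(cell("g_level"), cell("task"), cell("constant"),
      as.character(f$n),
      sprintf("%.*f", digits, f$r.squared),
      sprintf("%.*f", digits, f$adj.r.squared),
      sprintf("%.*f", digits, f$sigma),
      if (is.finite(fs["value"])) {
        sprintf("%.*f%s", digits, fs["value"], stars_for(fs["p.value"], star_legend))
      } else "NA")
  })
  out <- do.call(cbind, cols)
  rownames(out) <- report_row_names()
  colnames(out) <- names(fits)
  class(out) <- c("com_report", class(out))
  out
}

report_row_names <- function() {
  c("G-level", "Task", "Constant", "Observations", "R2", "Adjusted R2",
    "Residual Std. Error", "F Statistic")
}

stars_for <- function(p, legend) {
  if (!is.finite(p)) return("")
  for (i in seq_along(legend)) if (p < legend[i]) return(names(legend)[i])
  ""
}

#' @export
print.com_report <- function(x, ...) {
  m <- unclass(x)
  tab <- cbind(Variable = rownames(m), m)
  widths <- apply(nchar(tab), 2L, max)
  for (r in seq_len(nrow(tab))) {
    cells <- vapply(seq_along(widths), function(j)
      formatC(tab[r, j], width = widths[j], flag = "-"), character(1))
    cat(paste(cells, collapse = "  "), "\n")
  }
  invisible(x)
}

#' Parse a rendered report back into numbers
#'
#' Inverse of [table3_report()] up to formatting precision; used to verify
#' render/parse consistency.
#'
#' @param report a `com_report` object.
#' @return List per column: `g_level`, `task`, `constant` (each
#'   `c(estimate, se)`), `n`, `r.squared`, `adj.r.squared`, `sigma`, `f`.
#' @export
parse_report <- function(report) {
  m <- unclass(report)
  num <- function(s) suppressWarnings(as.numeric(gsub("[*]", "", s)))
  cell <- function(s) {
    if (s == "NA") return(c(estimate = NA_real_, se = NA_real_))
    parts <- regmatches(s, regexec("^(-?[0-9.]+)\\*{0,3} \\((-?[0-9.]+)\\)$", s))[[1]]
    c(estimate = as.numeric(parts[2]), se = as.numeric(parts[3]))
  }
  lapply(stats::setNames(seq_len(ncol(m)), colnames(m)), function(j) {
    list(g_level = cell(m["G-level", j]), task = cell(m["Task", j]),
         constant = cell(m["Constant", j]),
         n = as.integer(m["Observations", j]),
         r.squared = num(m["R2", j]),
         adj.r.squared = num(m["Adjusted R2", j]),
         sigma = num(m["Residual Std. Error", j]),
         f = num(m["F Statistic", j]))
  })
}
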
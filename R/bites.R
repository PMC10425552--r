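#' Bite sequence: one meal's bite-level record
#'
#' An ordered set of per-bite timestamps (minutes from meal start) and
#' cumulative intake (g), the basic data unit of the package. Invariants
#' enforced on construction: timings strictly increasing, positive, and at
#' most `meal_duration`; cumulative intake non-negative and non-decreasing,
#' with the final value equal to the meal's total intake.
#'
#' @param case_id identifier for the meal/case
#' @param times bite timestamps (min), strictly increasing, in (0, meal_duration]
#' @param intake cumulative intake at each bite (g), non-decreasing
#' @param meal_duration meal duration (min); defaults to the last bite time
#' @param validate check invariants (default `TRUE`)
#' @return An object of class `"bite_sequence"` with fields `case_id`,
#'   `times`, `intake`, `meal_duration`, `bite_count`.
#' @seealso [read_bite_csv()], [write_bite_csv()]
#' @export
#' @examples
#' bite_sequence("m1", times = c(1, 2.5, 4), intake = c(10, 20, 30))
bite_sequence <- function(case_id, times, intake,
                          meal_duration = max(times), validate = TRUE) {
  x <- structure(list(case_id = as.character(case_id),
                      times = as.numeric(times),
                      intake = as.numeric(intake),
                      meal_duration = as.numeric(meal_duration),
                      bite_count = length(times)),
                 class = "bite_sequence")
  if (validate) validate_bite_sequence(x)
  x
}

#' Validate a bite sequence
#'
#' Checks the bite-sequence invariants and reports the first violated bite
#' row in the error message.
#'
#' @param x a [bite_sequence()] object
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_bite_sequence <- function(x) {
  stopifnot(inherits(x, "bite_sequence"))
  fail <- function(row, what)
    stop(sprintf("invalid bite sequence '%s' at bite %d: %s",
                 x$case_id, row, what), call. = FALSE)
  n <- x$bite_count
  if (n < 1L) stop("empty bite sequence", call. = FALSE)
  if (length(x$intake) != n)
    stop("times and intake must have equal length", call. = FALSE)
  if (!all(is.finite(x$times))) fail(which(!is.finite(x$times))[1L], "non-finite time")
  if (!all(is.finite(x$intake))) fail(which(!is.finite(x$intake))[1L], "non-finite intake")
  if (any(x$times <= 0)) fail(which(x$times <= 0)[1L], "bite time not positive")
  bad <- which(diff(x$times) <= 0)
  if (length(bad)) fail(bad[1L] + 1L, "bite times not strictly increasing")
  tol <- 1e-8 * max(x$meal_duration, 1)
  bad <- which(x$times > x$meal_duration + tol)
  if (length(bad)) fail(bad[1L], "bite time exceeds meal duration")
  if (any(x$intake < 0)) fail(which(x$intake < 0)[1L], "negative cumulative intake")
  bad <- which(diff(x$intake) < 0)
  if (length(bad)) fail(bad[1L] + 1L, "cumulative intake decreasing")
  invisible(x)
}

#' @export
print.bite_sequence <- function(x, ...) {
  cat(sprintf("Bite sequence '%s': %d bites, %.1f g over %.2f min\n",
              x$case_id, x$bite_count, x$intake[x$bite_count],
              x$meal_duration))
  invisible(x)
}

#' @export
as.data.frame.bite_sequence <- function(x, ...) {
  data.frame(case_id = x$case_id,
             bite = seq_len(x$bite_count),
             time_min = x$times,
             intake_g = x$intake,
             stringsAsFactors = FALSE)
}

#' Read bite sequences from CSV
#'
#' Reads the package's bite-level CSV dialect: columns
#' `case_id, bite, time_min, intake_g` (header required; `bite` is the
#' 1-based bite ordinal within a case). Rows are ordered by bite within
#' case and every case is validated against the bite-sequence invariants;
#' the first violated row is reported.
#'
#' @param path path to a CSV file
#' @return a named list of [bite_sequence()] objects, one per case
#' @export
read_bite_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "bite", "time_min", "intake_g")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("bite CSV is missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- lapply(split(df, df$case_id), function(d) {
    d <- d[order(d$bite), , drop = FALSE]
    if (!identical(as.integer(d$bite), seq_len(nrow(d))))
      stop(sprintf("case '%s': bite ordinals must be 1..n", d$case_id[1L]),
           call. = FALSE)
    bite_sequence(d$case_id[1L], d$time_min, d$intake_g)
  })
  out[unique(df$case_id)]
}

#' Write bite sequences to CSV
#'
#' @param x a [bite_sequence()] or list of them
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_bite_csv <- function(x, path) {
  if (inherits(x, "bite_sequence")) x <- list(x)
  df <- do.call(rbind, lapply(x, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
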
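#' Parse PSMC text output
#'
#' Reads the standard `.psmc` dialect: iteration blocks introduced by `RD`
#' records, each carrying a `TR theta0 rho0` record and `RS k t_k lambda_k ...`
#' records giving the step function of scaled times (units of 2 N0
#' generations) and relative sizes.  `PA`, `//` and comment records are
#' skipped silently; genuinely unknown record types are skipped with one
#' warning.  The last `RD` block is the final iteration (PSMC convention);
#' earlier blocks are retained for diagnostics.
#'
#' @param input path to a `.psmc` file, a connection, or a character vector of
#'   lines.
#' @return An object of class `"psmc_document"`: list with `iterations` (each
#'   a list `theta0`, `rho0`, `t`, `lambda`) and `final` (index of the final
#'   iteration).
#' @export
read_psmc <- function(input) {
  lines <- if (is.character(input) && length(input) == 1 &&
               !grepl("\n", input) && file.exists(input)) readLines(input)
           else if (inherits(input, "connection")) readLines(input)
           else unlist(strsplit(as.character(input), "\n"))
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty PSMC input", call. = FALSE)
  known_skip <- c("PA", "CC", "MM", "DC", "TC", "IT", "//", "RR", "EX", "LK", "QD")
  iterations <- list()
  cur <- NULL
  warned <- character(0)
  flush <- function() if (!is.null(cur)) iterations[[length(iterations) + 1L]] <<- cur
  for (ln in lines) {
    f <- strsplit(trimws(ln), "[ \t]+")[[1]]
    tag <- f[1]
    if (tag == "RD") {
      flush()
      cur <- list(theta0 = NA_real_, rho0 = NA_real_,
                  t = numeric(0), lambda = numeric(0))
    } else if (tag == "TR") {
      if (is.null(cur)) cur <- list(theta0 = NA_real_, rho0 = NA_real_,
                                    t = numeric(0), lambda = numeric(0))
      cur$theta0 <- as.numeric(f[2])
      cur$rho0 <- as.numeric(f[3])
    } else if (tag == "RS") {
      if (is.null(cur)) cur <- list(theta0 = NA_real_, rho0 = NA_real_,
                                    t = numeric(0), lambda = numeric(0))
      cur$t <- c(cur$t, as.numeric(f[3]))
      cur$lambda <- c(cur$lambda, as.numeric(f[4]))
    } else if (tag %in% known_skip || startsWith(tag, "#")) {
      # structural / log records, not needed for the curve
    } else if (!(tag %in% warned)) {
      warning("ignoring unknown PSMC record type: ", tag, call. = FALSE)
      warned <- c(warned, tag)
    }
  }
  flush()
  if (length(iterations) == 0) stop("no RD/TR/RS records found", call. = FALSE)
  fin <- iterations[[length(iterations)]]
  if (!is.finite(fin$theta0))
    stop("missing TR record in final block", call. = FALSE)
  if (length(fin$t) == 0)
    stop("missing RS records in final block", call. = FALSE)
  if (fin$theta0 <= 0) stop("non-positive theta0 in final block", call. = FALSE)
  if (fin$t[1] != 0) stop("final block: t_0 must be 0", call. = FALSE)
  if (any(diff(fin$t) <= 0))
    stop("final block: RS times must be strictly increasing", call. = FALSE)
  if (any(fin$lambda <= 0))
    stop("final block: lambda values must be > 0", call. = FALSE)
  structure(list(iterations = iterations, final = length(iterations)),
            class = "psmc_document")
}

#' @export
#' @describeIn read_psmc re-serializes a parsed document; `%.17g` formatting
#'   round-trips doubles exactly, so `format(read_psmc(format(doc)))` is
#'   bitwise identical to `format(doc)`.
format.psmc_document <- function(x, ...) {
  unlist(lapply(seq_along(x$iterations), function(i) {
    it <- x$iterations[[i]]
    c(sprintf("RD %d", i - 1L),
      sprintf("TR %.17g %.17g", it$theta0, it$rho0),
      sprintf("RS %d %.17g %.17g", seq_along(it$t) - 1L, it$t, it$lambda),
      "//")
  }))
}

#' @export
print.psmc_document <- function(x, ...) {
  fin <- x$iterations[[x$final]]
  cat(sprintf("PSMC document: %d iteration block(s); final block: theta0 = %g, rho0 = %g, %d steps\n",
              length(x$iterations), fin$theta0, fin$rho0, length(fin$t)))
  invisible(x)
}

#' Rescale a PSMC document to years and diploid Ne
#'
#' Applies the standard PSMC rescaling: N0 = theta0 / (4 mu s) with s the
#' input bin size; each step start becomes 2 N0 t_k g years and each relative
#' size lambda_k becomes N0 lambda_k diploids.
#'
#' @param doc a [read_psmc()] result.
#' @param scaling a [scaling_config()] (mu, generation time, bin size).
#' @param iteration which block to scale (default: the final iteration).
#' @return a step [iicr_curve()] in (years, effective_size) with attributes
#'   `N0` and `theta0`.  The time axis keeps `t_0 = 0` as a leading step
#'   start; since a [time_grid()] must be positive, the first step is anchored
#'   at `t_1/2` of the second point when plotting/evaluating — evaluation
#'   before the first positive time returns the first value (right-continuous
#'   step convention), so no information is lost.
#' @export
scale_psmc <- function(doc, scaling = scaling_config(), iteration = NULL) {
  stopifnot(inherits(doc, "psmc_document"))
  it <- doc$iterations[[iteration %||% doc$final]]
  if (!is.finite(it$theta0) || it$theta0 <= 0)
    stop("non-positive theta0", call. = FALSE)
  N0 <- it$theta0 / (4 * scaling$mu * scaling$bin_size)
  years <- 2 * N0 * it$t * scaling$generation_time
  ne <- N0 * it$lambda
  # grid times must be > 0 and >= 2 points: anchor the t_0 = 0 step just
  # below the next one, and pad a constant (single-step) document rightwards
  tpos <- years
  if (length(tpos) == 1L) {
    tpos <- c(scaling$generation_time, 2 * N0 * scaling$generation_time)
    years <- c(years, tpos[2])
    ne <- rep(ne, 2)
  } else if (tpos[1] == 0) {
    tpos[1] <- tpos[2] / 100
  }
  out <- iicr_curve(time_grid(tpos, unit = "years"), ne,
                    value_unit = "effective_size", step = TRUE)
  attr(out, "N0") <- N0
  attr(out, "theta0") <- it$theta0
  attr(out, "step_starts_years") <- years
  out
}

#' Write a panmictic history as PSMC text
#'
#' Produces a minimal single-iteration `.psmc` document whose final block
#' encodes `history` exactly under the given `theta0` and `scaling`:
#' t_k = start_generations / (2 N0) and lambda_k = Ne_k / N0 with
#' N0 = theta0 / (4 mu s).  `read_psmc()` followed by [scale_psmc()] on the
#' output recovers the history to full double precision.
#'
#' @param history a [panmictic_history()].
#' @param theta0 scaled mutation rate per bin (> 0).
#' @param rho0 scaled recombination rate (cosmetic; default `theta0 / 4`).
#' @param scaling a [scaling_config()].
#' @param file optional path; if given the text is written there.
#' @return character vector of `.psmc` lines (invisibly if `file` is given).
#' @export
write_psmc <- function(history, theta0, rho0 = theta0 / 4,
                       scaling = scaling_config(), file = NULL) {
  stopifnot(inherits(history, "panmictic_history"))
  if (!is.finite(theta0) || theta0 <= 0) stop("theta0 must be > 0", call. = FALSE)
  N0 <- theta0 / (4 * scaling$mu * scaling$bin_size)
  tk <- history$start_generations / (2 * N0)
  lk <- history$ne / N0
  lines <- c("RD 0",
             sprintf("TR %.17g %.17g", theta0, rho0),
             sprintf("RS %d %.17g %.17g", seq_along(tk) - 1L, tk, lk),
             "//")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Parse a PSMC atomic-interval pattern
#'
#' The `-p` pattern grammar: terms `a` or `a*b` joined by `+` (whitespace
#' allowed), each contributing `a` groups of `b` atomic intervals (b = 1 when
#' absent).  `"4+25*2+4+6"` therefore spans 4 + 50 + 4 + 6 = 64 atomic
#' intervals.
#'
#' @param pattern pattern string.
#' @return list with `total` (atomic interval count) and `groups`
#'   (data.frame of `n_groups`, `per_group` per term).
#' @examples
#' pattern_to_intervals("4+25*2+4+6")$total   # 64
#' pattern_to_intervals("64*1")$total         # 64
#' @export
pattern_to_intervals <- function(pattern) {
  terms <- strsplit(gsub("[[:space:]“”\"]", "", pattern), "+",
                    fixed = TRUE)[[1]]
  if (length(terms) == 0) stop("empty pattern", call. = FALSE)
  parse_term <- function(tm) {
    if (!grepl("^[0-9]+(\\*[0-9]+)?$", tm))
      stop("malformed pattern term: '", tm, "'", call. = FALSE)
    ab <- as.integer(strsplit(tm, "*", fixed = TRUE)[[1]])
    if (length(ab) == 1L) ab <- c(ab, 1L)
    ab
  }
  m <- vapply(terms, parse_term, integer(2))
  groups <- data.frame(n_groups = m[1, ], per_group = m[2, ],
                       row.names = NULL)
  list(total = sum(groups$n_groups * groups$per_group), groups = groups)
}
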
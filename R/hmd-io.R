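#' Read a Human Mortality Database 1x1 file
#'
#' Parses the whitespace-delimited HMD single-year layout (e.g. `Mx_1x1`,
#' `fltper_1x1` qx columns, or any file with columns `Year`, `Age` and
#' per-sex values after a descriptive header). The age label `"110+"` (or any
#' trailing `+`) is parsed to its opening age and flagged as a terminal open
#' interval; missing values `"."` become `NA` gaps that downstream fits
#' reject with a clear message. Ages are truncated to `0:max_age` (default
#' 100). The reader tolerates CRLF line endings and trailing whitespace.
#'
#' @param path Path to a local HMD-layout text file (HMD requires
#'   registration, so files are always supplied by the user; nothing is
#'   downloaded).
#' @param sex `"female"`, `"male"` or `"total"` -- which value column to take.
#'   Ignored when the file has a single `value` column.
#' @param kind Whether the chosen column holds probabilities (`qx` files) or
#'   central rates (`Mx` files). Rates can be converted with [mx_to_qx()].
#' @param max_age Oldest age retained (default 100).
#' @param population Label stored in each schedule's metadata (defaults to
#'   the file name).
#' @return A named list of [mortality_schedule()] objects, one per year.
#' @export
read_hmd_1x1 <- function(path, sex = c("female", "male", "total"),
                         kind = c("probability", "rate"), max_age = 100,
                         population = NULL) {
  sex <- match.arg(sex)
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  hdr <- grep("^\\s*Year\\s+Age\\b", lines)
  if (length(hdr) == 0L) {
    stop_io(sprintf("%s: no header line starting with 'Year  Age' found", path))
  }
  hdr <- hdr[1]
  cols <- strsplit(trimws(lines[hdr]), "\\s+")[[1]]
  body <- lines[seq(hdr + 1L, length(lines))]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) stop_io(sprintf("%s: no data rows after header", path))

  rows <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(rows) != length(cols))
  if (length(bad)) {
    stop_io(sprintf("%s: malformed row at line %d (%d fields, expected %d)",
                    path, hdr + bad[1], lengths(rows)[bad[1]], length(cols)))
  }
  m <- do.call(rbind, rows)
  colnames(m) <- cols
  value_col <- if ("value" %in% tolower(cols)) {
    cols[tolower(cols) == "value"][1]
  } else {
    pick <- c(female = "Female", male = "Male", total = "Total")[[sex]]
    if (!pick %in% cols) {
      stop_io(sprintf("%s: column '%s' not present (have: %s)",
                      path, pick, paste(cols, collapse = ", ")))
    }
    pick
  }

  year <- suppressWarnings(as.integer(m[, "Year"]))
  if (anyNA(year)) {
    stop_io(sprintf("%s: non-integer Year at line %d",
                    path, hdr + which(is.na(year))[1]))
  }
  age_lab <- m[, "Age"]
  terminal <- grepl("\\+$", age_lab)
  age <- suppressWarnings(as.numeric(sub("\\+$", "", age_lab)))
  if (anyNA(age)) {
    stop_io(sprintf("%s: unparseable Age label '%s' at line %d",
                    path, age_lab[which(is.na(age))[1]],
                    hdr + which(is.na(age))[1]))
  }
  raw <- m[, value_col]
  value <- suppressWarnings(as.numeric(raw))
  value[raw == "."] <- NA_real_
  notnum <- raw != "." & is.na(value)
  if (any(notnum)) {
    stop_io(sprintf("%s: unparseable value '%s' at line %d",
                    path, raw[which(notnum)[1]], hdr + which(notnum)[1]))
  }
  if (any(value < 0, na.rm = TRUE)) {
    stop_domain(sprintf("%s: negative mortality values", path))
  }

  population <- population %||% basename(path)
  keep <- age <= max_age & !terminal
  df <- data.frame(year = year[keep], age = age[keep], value = value[keep])
  out <- lapply(split(df, df$year), function(dd) {
    dd <- dd[order(dd$age), ]
    mortality_schedule(dd$age, dd$value, kind = kind,
                       population = population, year = dd$year[1], sex = sex)
  })
  out[order(as.integer(names(out)))]
}

#' Read a plain CSV mortality schedule
#'
#' Expects columns `age` and `value`, optionally `kind` (constant column,
#' `"probability"` or `"rate"`).
#'
#' @param path CSV path.
#' @param kind Value kind, overridden by a `kind` column if present.
#' @inheritParams read_hmd_1x1
#' @return A single [mortality_schedule()].
#' @export
read_schedule_csv <- function(path, kind = c("probability", "rate"),
                              population = NA_character_) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("age", "value") %in% names(df))) {
    stop_io(sprintf("%s: need columns age, value", path))
  }
  if ("kind" %in% names(df)) kind <- df$kind[1]
  mortality_schedule(df$age, df$value, kind = kind, population = population)
}

#' Write a mortality schedule to CSV
#'
#' Columns `age`, `value`, `kind`; round-trips through
#' [read_schedule_csv()].
#'
#' @param s A [mortality_schedule()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(s, path) {
  s <- as_schedule(s, kind = schedule_kind(s))
  readr::write_csv(
    tibble::tibble(age = s$age, value = s$value, kind = schedule_kind(s)),
    path)
  invisible(path)
}

#' Convert central death rates to death probabilities
#'
#' Standard one-year interval conversion `q = m / (1 + (1 - a_frac) m)`,
#' where `a_frac` is the average fraction of the interval lived by those
#' dying in it. Monotone increasing in `m` and bounded above by 1; terminal
#' open intervals get q = 1.
#'
#' @param m Central death rate(s), >= 0.
#' @param a_frac Fraction(s) in `[0, 1]` (default 0.5; 0.14 is the usual
#'   infant value).
#' @param terminal Logical (recycled): force q = 1 for open intervals.
#' @return Death probabilities in `[0, 1]`.
#' @export
mx_to_qx <- function(m, a_frac = 0.5, terminal = FALSE) {
  if (any(m < 0, na.rm = TRUE)) stop_domain("death rates must be >= 0")
  if (any(a_frac < 0 | a_frac > 1)) stop_domain("a_frac must lie in [0, 1]")
  q <- m / (1 + (1 - a_frac) * m)
  q <- pmin(q, 1)
  q[rep_len(terminal, length(q))] <- 1
  q
}

#' Convert a rate schedule to a probability schedule
#'
#' @param s A rate [mortality_schedule()].
#' @inheritParams mx_to_qx
#' @param a_frac_infant Separation factor applied at age 0 (default 0.14).
#' @return A probability [mortality_schedule()] with the same metadata.
#' @export
schedule_to_qx <- function(s, a_frac = 0.5, a_frac_infant = 0.14) {
  s <- as_schedule(s, kind = schedule_kind(s))
  if (schedule_kind(s) == "probability") return(s)
  af <- rep(a_frac, nrow(s))
  if (s$age[1] == 0) af[1] <- a_frac_infant
  meta <- schedule_meta(s)
  mortality_schedule(s$age, mx_to_qx(s$value, af), kind = "probability",
                     population = meta$population, year = meta$year,
                     sex = meta$sex)
}

#' Serialize parameters, fits, life tables and decompositions
#'
#' Parameters serialize to a flat JSON object keyed by symbol name; fits to
#' JSON with a nested `params` object; life tables to CSV with columns
#' `age, q, l, d, L, e`; decompositions to JSON or a one-row component CSV.
#' All round-trip at full precision: `read_*(write_*(x))` reproduces `x`
#' field for field.
#'
#' @param p,fit,lt,dec The object to write.
#' @param path Destination path.
#' @return `path` invisibly for writers; the reconstructed object for
#'   readers.
#' @name serialization
NULL

write_json_ <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname serialization
#' @export
write_params <- function(p, path) {
  if (!inherits(p, c("code_params", "siler_params"))) {
    stop_input("expected code_params or siler_params")
  }
  write_json_(c(list(model = if (inherits(p, "code_params")) "code" else "siler"),
                unclass(p)), path)
}

#' @rdname serialization
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- x$model %||% "code"
  x$model <- NULL
  if (identical(model, "siler")) {
    do.call(siler_params, x[c("a1", "a2", "c", "b", "M")])
  } else {
    do.call(code_params, x[c("A", "B", "a", "b1", "b2", "b3", "M", "h", "g", "m_hump")])
  }
}

#' @rdname serialization
#' @export
write_life_table <- function(lt, path) {
  if (!inherits(lt, "life_table")) stop_input("expected a life_table")
  readr::write_csv(tibble::as_tibble(lt)[, c("age", "q", "l", "d", "L", "e")], path)
  invisible(path)
}

#' @rdname serialization
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("age", "q", "l", "d", "L", "e")
  if (!all(need %in% names(df))) {
    stop_io(sprintf("%s: need columns %s", path, paste(need, collapse = ", ")))
  }
  n <- nrow(df)
  l_next <- c(df$l[-1], df$l[n] * (1 - df$q[n]))
  af <- ifelse(df$d > 0, (df$L - l_next) / df$d, 0.5)
  out <- tibble::tibble(age = df$age, q = df$q, a_frac = af,
                        l = df$l, d = df$d, L = df$L, e = df$e)
  attr(out, "closure") <- if (df$q[n] == 1) "terminal-one" else "none"
  attr(out, "open_survivorship") <- df$l[n] * (1 - df$q[n])
  class(out) <- c("life_table", class(out))
  out
}

#' @rdname serialization
#' @export
write_fit <- function(fit, path) {
  if (!inherits(fit, "code_fit")) stop_input("expected a code_fit")
  write_json_(list(
    model = fit$model, params = unclass(fit$params), objective = fit$objective,
    r2_logq = fit$r2_logq, r2_d = fit$r2_d, r2_avg = fit$r2_avg,
    converged = fit$converged, n_evals = fit$n_evals,
    age_range = fit$age_range, seed = fit$seed), path)
}

#' @rdname serialization
#' @export
read_fit <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pars <- as.list(x$params)
  params <- if (identical(x$model, "siler")) {
    do.call(siler_params, pars[c("a1", "a2", "c", "b", "M")])
  } else {
    do.call(code_params, pars[c("A", "B", "a", "b1", "b2", "b3", "M", "h", "g", "m_hump")])
  }
  structure(list(model = x$model, params = params, objective = x$objective,
                 r2_logq = x$r2_logq, r2_d = x$r2_d, r2_avg = x$r2_avg,
                 converged = x$converged, n_evals = x$n_evals,
                 age_range = x$age_range, seed = x$seed),
            class = "code_fit")
}

#' @rdname serialization
#' @param format `"json"` or `"csv"` (one labelled component row).
#' @export
write_decomposition <- function(dec, path, format = c("json", "csv")) {
  if (!inherits(dec, "e0_decomposition")) stop_input("expected an e0_decomposition")
  format <- match.arg(format)
  if (format == "json") {
    write_json_(unclass(dec), path)
  } else {
    readr::write_csv(tibble::tibble(
      e0_start = dec$e0_start, e0_end_model = dec$e0_end_model,
      total_model = dec$e0_end_model - dec$e0_start,
      delay_of_mortality = dec$delta_delay,
      young_age = dec$delta_young,
      middle_age = dec$delta_middle,
      above_modal_age = dec$delta_old,
      unexplained = dec$unexplained %||% NA_real_), path)
  }
  invisible(path)
}

#' @rdname serialization
#' @export
read_decomposition <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$order <- as.character(x$order)
  structure(x, class = "e0_decomposition")
}
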
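# config keys: the reference-table symbols, with a single "q" accepted as a
# convenience that sets both zone catchabilities
.config_keys <- c("r", "K", "a", "c", "p", "q", "q1", "q2", "alpha", "V",
                  "delta_k", "beta0", "sigma", "gamma", "attraction_form",
                  "epsilon", "mu")

#' Read a parameter configuration file
#'
#' Loads a flat YAML or JSON file whose keys are the model's parameter
#' symbols (\code{r, K, a, c, p, q, alpha, V, delta_k, beta0, sigma, gamma})
#' plus \code{attraction_form}, \code{epsilon} and \code{mu}; \code{q} sets
#' both zone catchabilities, or \code{q1}/\code{q2} may be given separately.
#' Unknown keys are an error (no silent typo tolerance); \code{beta0} and
#' \code{delta_k} must be present, either in the file or as defaults
#' supplied by the caller.
#'
#' @param path file path; format chosen by extension (\code{.yaml} /
#'   \code{.yml} / \code{.json}).
#' @param defaults optional named list merged under the file's values
#'   (file wins), e.g. a preset's parameters.
#' @return a validated \code{reef_params} object.
#' @examples
#' path <- tempfile(fileext = ".yaml")
#' writeLines(c("V: 120", "beta0: 1", "delta_k: 5", "gamma: 0.05"), path)
#' read_reef_config(path)
#' @export
read_reef_config <- function(path, defaults = list()) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = ,
                yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("unsupported config format '.", ext,
                     "'; use .yaml, .yml or .json", call. = FALSE))
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) {
    stop("config must be a flat mapping of parameter names to values",
         call. = FALSE)
  }
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(.config_keys, collapse = ", "), call. = FALSE)
  }
  merged <- utils::modifyList(as.list(defaults), raw)
  if ("q" %in% names(merged)) {
    if (!"q1" %in% names(raw)) merged$q1 <- merged$q
    if (!"q2" %in% names(raw)) merged$q2 <- merged$q
    merged$q <- NULL
  }
  for (key in c("beta0", "delta_k")) {
    if (is.null(merged[[key]])) {
      stop("config must choose '", key,
           "' explicitly (the reference table lists two values)",
           call. = FALSE)
    }
  }
  do.call(reef_params, merged)
}

#' Write a parameter configuration file
#'
#' Serializes a parameter set to flat YAML or JSON using the same keys that
#' \code{\link{read_reef_config}} accepts; when the two zone catchabilities
#' are equal they are written as a single \code{q}. The round trip
#' config -> parameters -> config is lossless.
#'
#' @param params a \code{reef_params} object.
#' @param path output path (\code{.yaml} / \code{.yml} / \code{.json}).
#' @return \code{path}, invisibly.
#' @export
write_reef_config <- function(params, path) {
  params <- validate_reef_params(params)
  out <- unclass(params)
  if (out$q1 == out$q2) {
    out <- c(list(q = out$q1), out[setdiff(names(out), c("q1", "q2"))])
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         yaml = ,
         yml = yaml::write_yaml(out, path),
         json = jsonlite::write_json(out, path, auto_unbox = TRUE,
                                     digits = NA, pretty = TRUE),
         stop("unsupported config format '.", ext,
              "'; use .yaml, .yml or .json", call. = FALSE))
  invisible(path)
}

#' Write a sweep table or trajectory
#'
#' CSV (comma-separated, UTF-8, '.' decimal, no index column) or JSON
#' (array of records). Numeric columns are serialized with 10 significant
#' digits, so identical inputs produce byte-identical files.
#'
#' @param table data.frame (a sweep table, equilibrium record or
#'   \code{as.data.frame}'d trajectory); \code{reef_trajectory} and
#'   \code{reef_equilibrium} objects are converted automatically.
#' @param path output path.
#' @param format \code{"csv"} or \code{"json"}.
#' @param allow_empty permit writing a header-only table.
#' @return \code{path}, invisibly.
#' @examples
#' tab <- sweep_gamma(reef_params(beta0 = 1, delta_k = 5),
#'                    gamma_grid = c(0, 0.5), V = 120)
#' f <- tempfile(fileext = ".csv")
#' write_reef_table(tab, f)
#' @export
write_reef_table <- function(table, path, format = c("csv", "json"),
                             allow_empty = FALSE) {
  format <- match.arg(format)
  if (inherits(table, "reef_trajectory") ||
      inherits(table, "reef_equilibrium")) {
    table <- as.data.frame(table)
  }
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0L && !allow_empty) {
    stop("refusing to write an empty table (set allow_empty = TRUE)",
         call. = FALSE)
  }
  num <- vapply(table, is.double, logical(1))
  table[num] <- lapply(table[num], signif, digits = 10)
  if (format == "csv") {
    utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(table, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}

#' Read back a table written by \code{write_reef_table}
#'
#' @param path file path.
#' @param format \code{"csv"} or \code{"json"}; default guessed from the
#'   extension.
#' @return data.frame.
#' @export
read_reef_table <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  }
  if (format == "csv") {
    utils::read.csv(path, fileEncoding = "UTF-8")
  } else {
    jsonlite::fromJSON(path)
  }
}
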
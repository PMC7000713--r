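#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; blank lines and lines starting with
#' `#` are ignored.  Values are parsed as numbers where possible, as
#' logicals for `TRUE`/`FALSE`, otherwise kept as strings.
#'
#' @param path Path to the configuration file.
#' @return A named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed configuration line (no '='): ", ln)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    if (!nzchar(key)) stop("malformed configuration line (empty key): ", ln)
    out[[key]] <- .parse_config_value(val)
  }
  out
}

.parse_config_value <- function(val) {
  if (toupper(val) %in% c("TRUE", "FALSE")) return(as.logical(toupper(val)))
  num <- suppressWarnings(as.numeric(val))
  if (!is.na(num)) num else val
}

#' Write a flat key-value configuration file
#'
#' @param config Named list of scalar values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config), length(names(config)) == length(config))
  writeLines(paste(names(config), unlist(lapply(config, format)), sep = " = "),
             path)
  invisible(path)
}

# fetch a numeric config key, naming the key in every failure mode
config_number <- function(config, key, default = NULL) {
  if (is.null(config[[key]])) {
    if (is.null(default)) stop("missing configuration key '", key, "'")
    return(default)
  }
  val <- config[[key]]
  if (!is.numeric(val) || length(val) != 1 || !is.finite(val))
    stop("configuration key '", key, "' must be a single finite number, got: ",
         deparse(val))
  val
}

#' Content digest of a resolved configuration
#'
#' MD5 digest of the configuration serialized with sorted keys, so the
#' digest is stable under key reordering.
#'
#' @param config Named list.
#' @return A hex digest string.
#' @export
config_digest <- function(config) {
  keys <- sort(names(config))
  txt <- paste(keys, vapply(config[keys], function(v) paste(format(v), collapse = ","),
                            character(1)), sep = "=", collapse = "\n")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  unname(tools::md5sum(tmp))
}

#' Read / write herbivore community tables
#'
#' Delimited text with columns `mass_kg` and `density_per_km2`.
#'
#' @param path File path.
#' @param label Scenario label; defaults to the file name without extension.
#' @return [read_community()]: a [herbivore_community()];
#'   [write_community()]: `path`, invisibly.
#' @export
read_community <- function(path, label = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("mass_kg", "density_per_km2") %in% names(df)))
    stop("community file needs columns 'mass_kg' and 'density_per_km2'")
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  herbivore_community(df$mass_kg, df$density_per_km2, label = label)
}

#' @rdname read_community
#' @param community A [herbivore_community()].
#' @export
write_community <- function(community, path) {
  stopifnot(inherits(community, "herbivore_community"))
  utils::write.csv(as.data.frame(community), path, row.names = FALSE)
  invisible(path)
}

#' Read / write gridded domains as plain text
#'
#' A small self-describing text format: header lines `nx`, `ny`, `dx_km`,
#' then `ny` rows of `nx` cell codes (0 = non-land, 1 = land, 2 = source).
#'
#' @param path File path.
#' @return [read_grid_domain()]: a [grid_domain()];
#'   [write_grid_domain()]: `path`, invisibly.
#' @export
read_grid_domain <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  hdr <- lines[1:3]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, key)]
    if (length(ln) != 1) stop("grid file missing header '", key, "'")
    as.numeric(trimws(sub(key, "", ln, fixed = TRUE)))
  }
  nx <- as.integer(get("nx")); ny <- as.integer(get("ny")); dx <- get("dx_km")
  codes <- do.call(rbind, lapply(lines[3 + seq_len(ny)], function(ln)
    as.integer(strsplit(trimws(ln), "\\s+")[[1]])))
  if (!identical(dim(codes), c(ny, nx)))
    stop("grid body does not match declared ny x nx")
  grid_domain(nx, ny, dx, land_mask = codes >= 1L, source_mask = codes == 2L)
}

#' @rdname read_grid_domain
#' @param domain A [grid_domain()].
#' @export
write_grid_domain <- function(domain, path) {
  stopifnot(inherits(domain, "grid_domain"))
  codes <- matrix(0L, domain$ny, domain$nx)
  codes[domain$land_mask] <- 1L
  codes[domain$source_mask] <- 2L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# gridded domain: 0 = non-land, 1 = land, 2 = source",
               paste("nx", domain$nx), paste("ny", domain$ny),
               paste("dx_km", format(domain$dx))), con)
  writeLines(apply(codes, 1, paste, collapse = " "), con)
  invisible(path)
}
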
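# Plain-text mechanism file dialect.
#
#   # comment
#   modelname = Kondepudi-Nelson
#   species = L, D
#   reaction =       -> L
#   reaction = L + D ->
#   reaction = A    <-> B        # expands to forward then backward
#   dual_pairs = (0,1), (2,3)
#   enantiomeric_pairs = (0,1)
#   option sna.num-samples = 10
#
# A restricted key/value format, not executable code.  Reversible lines are
# expanded per line, forward then backward, and reaction indices are 0-based
# in emission order.

known_option_keys <- c(
  "enabled", "num-samples", "dual-pairs-in-ec", "instability-heuristic",
  "sum-mineurs", "max-mineur-search-stop", "simplification-tries",
  "samples-folder", "samples-for-proportion", "enantiomeric-pairs",
  "2by2-jacobian", "plot", "time-to-show-plot")

parse_pair_list <- function(value) {
  if (trimws(value) == "") return(list())
  m <- gregexpr("\\(\\s*[0-9]+\\s*,\\s*[0-9]+\\s*\\)", value)[[1]]
  if (m[1] == -1) stop("cannot parse index pair list: '", value, "'")
  lapply(regmatches(value, gregexpr(
    "\\(\\s*[0-9]+\\s*,\\s*[0-9]+\\s*\\)", value))[[1]], function(tok) {
      nums <- as.integer(strsplit(gsub("[()\\s]", "",
                                       gsub("[[:space:]]", "", tok)), ",")[[1]])
      nums
    })
}

parse_option_value <- function(value) {
  v <- trimws(value)
  if (tolower(v) %in% c("true", "t")) return(TRUE)
  if (tolower(v) %in% c("false", "f")) return(FALSE)
  if (grepl("^\\(", v)) return(parse_pair_list(v))
  if (grepl("^-?[0-9]+$", v)) return(as.integer(v))
  if (grepl("^-?[0-9]*\\.[0-9]+$", v)) return(as.numeric(v))
  gsub("^['\"]|['\"]$", "", v)
}

#' Read a mechanism model file
#'
#' @param path path to a plain-text model file.
#' @param strict when `TRUE`, unknown option keys are an error instead of a
#'   warning.
#' @return a validated [reaction_network()] whose `options` field holds the
#'   per-algorithm option map.
#' @export
parse_model <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("model file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[trimws(lines) != ""]

  name <- NULL; species <- NULL
  rx_lines <- character(0)
  dual_pairs <- NULL; en_pairs <- NULL
  options <- list()

  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("cannot parse model line (no '='): '", ln, "'")
    key <- trimws(substr(ln, 1, eq - 1))
    value <- substr(ln, eq + 1, nchar(ln))
    if (key == "modelname") {
      name <- gsub("^['\"]|['\"]$", "", trimws(value))
    } else if (key == "species") {
      species <- trimws(strsplit(trimws(value), "[,[:space:]]+")[[1]])
      species <- species[species != ""]
    } else if (key == "reaction") {
      rx_lines <- c(rx_lines, value)
    } else if (key == "dual_pairs") {
      dual_pairs <- parse_pair_list(value)
    } else if (key == "enantiomeric_pairs") {
      en_pairs <- parse_pair_list(value)
    } else if (grepl("^option[[:space:]]", key)) {
      spec <- trimws(sub("^option[[:space:]]+", "", key))
      dot <- regexpr(".", spec, fixed = TRUE)
      if (dot < 0) stop("option key must be '<algorithm>.<key>': ", spec)
      alg <- substr(spec, 1, dot - 1)
      opt <- substr(spec, dot + 1, nchar(spec))
      if (!opt %in% known_option_keys) {
        msg <- paste0("unknown option key '", opt, "' for algorithm '",
                      alg, "'")
        if (strict) stop(msg) else warning(msg, call. = FALSE)
      }
      if (is.null(options[[alg]])) options[[alg]] <- list()
      options[[alg]][[opt]] <- parse_option_value(value)
    } else {
      msg <- paste0("unknown model file key: '", key, "'")
      if (strict) stop(msg) else warning(msg, call. = FALSE)
    }
  }

  if (is.null(name)) stop("model file declares no modelname")
  if (is.null(species)) stop("model file declares no species")
  if (length(rx_lines) == 0L) stop("model file declares no reactions")

  parsed <- lapply(rx_lines, parse_reaction)
  reactions <- expand_reversibles(parsed)
  reaction_network(
    name = name, species = species, reactions = reactions,
    enantiomeric_pairs = en_pairs %||% list(c(0L, 1L)),
    dual_pairs = dual_pairs, options = options)
}

#' Serialize a reaction network back to the model-file dialect
#'
#' Reactions are written pre-expanded (all irreversible), so a
#' parse -> write -> parse round trip reproduces the identical network.
#'
#' @param network a `reaction_network`.
#' @param path output file path.
#' @export
write_model <- function(network, path) {
  fmt_pairs <- function(pairs)
    paste(vapply(pairs, function(p) sprintf("(%d,%d)", p[1], p[2]),
                 character(1)), collapse = ", ")
  lines <- c(
    paste("modelname =", network$name),
    paste("species =", paste(network$species, collapse = ", ")),
    vapply(network$reactions, function(r)
      paste("reaction =", format_reaction(r)), character(1)),
    paste("enantiomeric_pairs =", fmt_pairs(network$enantiomeric_pairs)))
  if (length(network$dual_pairs))
    lines <- c(lines, paste("dual_pairs =", fmt_pairs(network$dual_pairs)))
  for (alg in names(network$options)) {
    for (opt in names(network$options[[alg]])) {
      v <- network$options[[alg]][[opt]]
      vs <- if (is.logical(v)) ifelse(v, "true", "false")
            else if (is.list(v)) fmt_pairs(v)
            else as.character(v)
      lines <- c(lines, sprintf("option %s.%s = %s", alg, opt, vs))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
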
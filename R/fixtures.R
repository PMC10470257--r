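# Bundled mechanism library: the classical and recent homochirality
# models shipped as plain-text fixtures under extdata/models.

#' List bundled model fixtures
#' @return character vector of fixture names.
#' @export
list_fixtures <- function() {
  dir <- system.file("extdata", "models", package = "chiralstab")
  sort(sub("\\.txt$", "", list.files(dir, pattern = "\\.txt$")))
}

#' Load a bundled model fixture
#'
#' @param name fixture name (see [list_fixtures()]).
#' @param dual_pairs optional replacement dual-pair list (0-based index
#'   pairs), e.g. to force autocatalytic and LES rates equal in the LES
#'   model.
#' @return a `reaction_network`.
#' @export
load_fixture <- function(name, dual_pairs = NULL) {
  dir <- system.file("extdata", "models", package = "chiralstab")
  path <- file.path(dir, paste0(name, ".txt"))
  if (!file.exists(path))
    stop("unknown fixture '", name, "'; available: ",
         paste(list_fixtures(), collapse = ", "))
  net <- parse_model(path)
  if (!is.null(dual_pairs)) {
    net <- reaction_network(
      name = net$name, species = net$species, reactions = net$reactions,
      enantiomeric_pairs = net$enantiomeric_pairs,
      dual_pairs = dual_pairs, options = net$options)
  }
  net
}
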
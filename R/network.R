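# Reaction-network representation.
#
# A network couples an ordered species list (the first two species are
# always an enantiomeric pair) with an ordered list of irreversible
# mass-action reactions.  Reactions that map onto each other under the
# mirror swap of enantiomer partners are "dual pairs" and must share a rate
# constant; rate equalities involving more than two reactions (e.g. a
# common CSTR flow constant) are encoded as pairs sharing the same first
# element: (i, a), (i, b), (i, c), ...

#' Parse a single reaction line
#'
#' Grammar: `side := "" | term ("+" term)*`, `term := [integer] species`,
#' with `->` (irreversible) or `<->` (reversible) between the sides.
#' Stoichiometric coefficients are space-separated positive integers
#' (`"2 L"`); tokens may not start with a digit, so `"2L"` is rejected
#' rather than read as a coefficient.
#'
#' @param line character scalar, e.g. `"L + D -> "` or `" <-> L"`.
#' @return list with `reactants` and `products` (named integer multisets,
#'   name = species, value = coefficient) and logical `reversible`.
#' @export
#' @examples
#' parse_reaction("L + D -> ")
#' parse_reaction(" <-> L")
parse_reaction <- function(line) {
  stopifnot(is.character(line), length(line) == 1L)
  raw <- sub("#.*$", "", line)
  reversible <- grepl("<->", raw, fixed = TRUE)
  parts <- if (reversible) strsplit(raw, "<->", fixed = TRUE)[[1]]
           else strsplit(raw, "->", fixed = TRUE)[[1]]
  if (!reversible && !grepl("->", raw, fixed = TRUE))
    stop("malformed reaction (no arrow): '", line, "'")
  if (length(parts) > 2L)
    stop("malformed reaction (multiple arrows): '", line, "'")
  lhs <- if (length(parts) >= 1L) parts[1] else ""
  rhs <- if (length(parts) == 2L) parts[2] else ""
  list(reactants = parse_side(lhs, line),
       products  = parse_side(rhs, line),
       reversible = reversible)
}

parse_side <- function(side, line) {
  side <- trimws(side)
  out <- integer(0)
  if (side == "") return(out)
  for (term in trimws(strsplit(side, "+", fixed = TRUE)[[1]])) {
    if (term == "") stop("empty term in reaction: '", line, "'")
    toks <- strsplit(term, "[[:space:]]+")[[1]]
    if (length(toks) == 1L) {
      coef <- 1L; name <- toks[1]
    } else if (length(toks) == 2L) {
      if (!grepl("^[0-9]+$", toks[1]))
        stop("bad coefficient '", toks[1], "' in reaction: '", line, "'")
      coef <- as.integer(toks[1]); name <- toks[2]
    } else {
      stop("cannot parse term '", term, "' in reaction: '", line, "'")
    }
    if (coef < 1L)
      stop("non-positive coefficient in reaction: '", line, "'")
    if (grepl("^[0-9]", name))
      stop("species token may not start with a digit ('", name,
           "') in reaction: '", line, "'; write coefficients as '2 X'")
    if (grepl("[[:space:]]", name))
      stop("species token contains whitespace in reaction: '", line, "'")
    if (name %in% names(out)) out[name] <- out[name] + coef
    else { out <- c(out, stats::setNames(coef, name)) }
  }
  out
}

#' Expand reversible lines into an ordered irreversible reaction list
#'
#' Each reversible line contributes its forward reaction immediately
#' followed by its backward reaction; indices are assigned 0-based in
#' emission order.
#'
#' @param parsed list of results of [parse_reaction()] in file order.
#' @return list of `list(reactants, products, line)` irreversible reactions.
#' @export
expand_reversibles <- function(parsed) {
  out <- list()
  for (li in seq_along(parsed)) {
    p <- parsed[[li]]
    out[[length(out) + 1L]] <-
      list(reactants = p$reactants, products = p$products)
    if (isTRUE(p$reversible))
      out[[length(out) + 1L]] <-
        list(reactants = p$products, products = p$reactants)
  }
  out
}

multiset_equal <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (length(a) == 0L) return(TRUE)
  a <- a[order(names(a))]; b <- b[order(names(b))]
  identical(names(a), names(b)) && all(a == b)
}

reaction_equal <- function(r1, r2) {
  multiset_equal(r1$reactants, r2$reactants) &&
    multiset_equal(r1$products, r2$products)
}

# Species-name permutation swapping each declared enantiomeric pair.
swap_map <- function(species, pairs) {
  map <- stats::setNames(species, species)
  for (p in pairs) {
    a <- species[p[1] + 1L]; b <- species[p[2] + 1L]
    map[a] <- b; map[b] <- a
  }
  map
}

mirror_reaction <- function(rx, map) {
  rn <- rx
  names(rn$reactants) <- unname(map[names(rx$reactants)])
  names(rn$products)  <- unname(map[names(rx$products)])
  rn
}

#' Detect dual reaction pairs by mirror symmetry of the first enantiomeric pair
#'
#' Reaction i pairs with reaction j (i < j) when swapping the two species of
#' the first enantiomeric pair turns i into exactly j (as multisets).
#' Reactions invariant under the swap are regular.
#'
#' @param reactions list of irreversible reactions.
#' @param species character vector of species names.
#' @param first_pair 0-based index pair, default `c(0, 1)`.
#' @return list of 0-based index pairs `c(i, j)`, i < j.
#' @export
detect_dual_pairs <- function(reactions, species, first_pair = c(0L, 1L)) {
  map <- swap_map(species, list(first_pair))
  n <- length(reactions)
  used <- rep(FALSE, n)
  pairs <- list()
  for (i in seq_len(n)) {
    if (used[i]) next
    mi <- mirror_reaction(reactions[[i]], map)
    if (reaction_equal(mi, reactions[[i]])) next    # self-mirror -> regular
    for (j in seq_len(n)) {
      if (j == i || used[j]) next
      if (reaction_equal(mi, reactions[[j]])) {
        pairs[[length(pairs) + 1L]] <- c(min(i, j) - 1L, max(i, j) - 1L)
        used[i] <- used[j] <- TRUE
        break
      }
    }
  }
  pairs[order(vapply(pairs, `[`, integer(1), 1L),
              vapply(pairs, `[`, integer(1), 2L))]
}

# Union-find grouping of rate-equality pairs.
dual_groups_from_pairs <- function(pairs, n_reactions) {
  parent <- seq_len(n_reactions)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (p in pairs) {
    a <- find(p[1] + 1L); b <- find(p[2] + 1L)
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(n_reactions), find, integer(1))
  groups <- split(seq_len(n_reactions) - 1L, roots)
  groups <- groups[vapply(groups, length, integer(1)) > 1L]
  unname(groups[order(vapply(groups, min, integer(1)))])
}

normalize_dual_pairs <- function(groups) {
  out <- list()
  for (g in groups) {
    g <- sort(g)
    for (other in g[-1]) out[[length(out) + 1L]] <- c(g[1], other)
  }
  out
}

#' Construct and validate a reaction network
#'
#' @param name model name.
#' @param species ordered character vector; the first two species must form
#'   an enantiomeric pair.
#' @param reactions list of irreversible reactions
#'   (`list(reactants, products)` named-integer multisets), already expanded.
#' @param enantiomeric_pairs list of 0-based index pairs; the first must be
#'   `c(0, 1)`.
#' @param dual_pairs optional list of 0-based reaction-index pairs declaring
#'   rate equalities, merged with the automatically detected mirror pairs.
#' @param options nested option list keyed by algorithm name.
#' @return object of class `reaction_network`.
#' @export
reaction_network <- function(name, species, reactions,
                             enantiomeric_pairs = list(c(0L, 1L)),
                             dual_pairs = NULL, options = list()) {
  if (length(species) < 2L)
    stop("a network needs at least 2 species (an enantiomeric pair)")
  if (anyDuplicated(species))
    stop("duplicate species names")
  if (length(reactions) == 0L)
    stop("empty reaction list")
  enantiomeric_pairs <- lapply(enantiomeric_pairs, as.integer)
  if (!identical(enantiomeric_pairs[[1]], c(0L, 1L)))
    stop("the first enantiomeric pair must be the first two species (0, 1)")
  for (p in enantiomeric_pairs) {
    if (length(p) != 2L || p[1] == p[2] ||
        any(p < 0L) || any(p >= length(species)))
      stop("invalid enantiomeric pair: (", paste(p, collapse = ","), ")")
  }
  flat <- unlist(enantiomeric_pairs)
  if (anyDuplicated(flat))
    stop("a species occurs in more than one enantiomeric pair")
  unknown <- setdiff(unique(unlist(lapply(reactions, function(r)
    c(names(r$reactants), names(r$products))))), species)
  if (length(unknown))
    stop("reaction references undeclared species: ",
         paste(unknown, collapse = ", "))

  nrx <- length(reactions)
  detected <- detect_dual_pairs(reactions, species)
  declared <- lapply(dual_pairs %||% list(), as.integer)
  for (p in declared) {
    if (length(p) != 2L || p[1] == p[2] || any(p < 0L) || any(p >= nrx))
      stop("invalid dual pair: (", paste(p, collapse = ","), ")")
  }
  groups <- dual_groups_from_pairs(c(detected, declared), nrx)

  # Every rate-equality group must be closed under the joint mirror swap of
  # all declared enantiomeric pairs; otherwise a declared pair ties together
  # reactions that are not mirror-compatible.
  map_all <- swap_map(species, enantiomeric_pairs)
  mirror_idx <- integer(nrx)
  for (i in seq_len(nrx)) {
    mi <- mirror_reaction(reactions[[i]], map_all)
    hit <- which(vapply(reactions, reaction_equal, logical(1), r2 = mi))
    mirror_idx[i] <- if (length(hit)) hit[1] else NA_integer_
  }
  for (g in groups) {
    mg <- mirror_idx[g + 1L] - 1L
    if (anyNA(mg) || !all(mg %in% g))
      stop("declared dual pairs are not mirror images under the declared ",
           "enantiomeric pairs (group: ", paste(g, collapse = ","), ")")
  }

  in_group <- sort(unique(unlist(groups)))
  regular <- setdiff(seq_len(nrx) - 1L, in_group)
  structure(list(
    name = name,
    species = species,
    reactions = reactions,
    enantiomeric_pairs = enantiomeric_pairs,
    dual_pairs = normalize_dual_pairs(groups),
    dual_groups = groups,
    regular_reactions = regular,
    options = options
  ), class = "reaction_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.reaction_network <- function(x, ...) {
  cat("Reaction network:", x$name, "\n")
  cat("  species (", length(x$species), "): ",
      paste(x$species, collapse = ", "), "\n", sep = "")
  cat("  reactions (", length(x$reactions), "):\n", sep = "")
  for (i in seq_along(x$reactions))
    cat(sprintf("   %2d. %s\n", i - 1L, format_reaction(x$reactions[[i]])))
  cat("  enantiomeric pairs:",
      paste(vapply(x$enantiomeric_pairs, function(p)
        sprintf("(%d,%d)", p[1], p[2]), character(1)), collapse = " "), "\n")
  cat("  dual pairs:",
      paste(vapply(x$dual_pairs, function(p)
        sprintf("(%d,%d)", p[1], p[2]), character(1)), collapse = " "), "\n")
  cat("  regular reactions:",
      paste(x$regular_reactions, collapse = " "), "\n")
  invisible(x)
}

format_side <- function(side) {
  if (length(side) == 0L) return("")
  paste(ifelse(side == 1L, names(side), paste(side, names(side))),
        collapse = " + ")
}

format_reaction <- function(r) {
  paste(format_side(r$reactants), "->", format_side(r$products))
}

#' Map each reaction to its dual-pair representative rate index
#'
#' All members of a rate-equality group share the rate symbol of the
#' group's smallest member.
#' @param network a `reaction_network`.
#' @return integer vector, 0-based representative index per reaction.
#' @export
rate_representatives <- function(network) {
  rep <- seq_along(network$reactions) - 1L
  for (g in network$dual_groups) rep[g + 1L] <- min(g)
  rep
}
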
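# Reaction fingerprints, Tanimoto similarity and the three-mode subset
# search. Binary reaction fingerprints combine the per-side molecular
# fingerprints (bitwise union over molecules of a side) either by
# concatenation (reactant block then product block) or by a further union
# ("sum"); the difference mode keeps per-side bit counts and stores the
# elementwise absolute difference |product - reactant|. Agents never enter a
# fingerprint.

FP_BASE_LEN <- c(maccs = 166L, ecfp4 = 1024L)

#' Compute a reaction fingerprint
#'
#' @param rxn an \code{rxn_reaction}.
#' @param scheme \code{"maccs"} (166-bit structural keys) or \code{"ecfp4"}
#'   (1024-bit circular fingerprint, radius 2).
#' @param mode \code{"concat"} (default; length 2 x base), \code{"sum"}
#'   (bitwise union, base length) or \code{"difference"} (integer count
#'   vector, base length).
#' @return an object of class \code{rxn_fingerprint}: \code{scheme},
#'   \code{mode}, \code{vector} (integer 0/1 or counts).
#' @export
reaction_fingerprint <- function(rxn, scheme = c("maccs", "ecfp4"),
                                 mode = c("concat", "sum", "difference")) {
  reaction_fingerprints(list(rxn), scheme, mode)[[1L]]
}

#' Vectorized reaction fingerprints (one worker round trip)
#' @inheritParams reaction_fingerprint
#' @param rxns list of \code{rxn_reaction} objects.
#' @return list of \code{rxn_fingerprint} objects.
#' @export
reaction_fingerprints <- function(rxns, scheme = c("maccs", "ecfp4"),
                                  mode = c("concat", "sum", "difference")) {
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  if (!length(rxns)) return(list())
  base <- FP_BASE_LEN[[scheme]]
  counts <- mode == "difference"
  sets <- list()
  for (rxn in rxns) {
    sets[[length(sets) + 1L]] <- lapply(rxn$reactants, function(m) m$csmiles)
    sets[[length(sets) + 1L]] <- lapply(rxn$products, function(m) m$csmiles)
  }
  res <- chem_call1(list(op = "fp", scheme = scheme, counts = counts,
                         smiles_sets = sets))
  out <- vector("list", length(rxns))
  for (k in seq_along(rxns)) {
    r <- res[[2L * k - 1L]]; p <- res[[2L * k]]
    rv <- integer(base); pv <- integer(base)
    rb <- as.integer(unlist(r$bits)) + 1L
    pb <- as.integer(unlist(p$bits)) + 1L
    if (counts) {
      rv[rb] <- as.integer(unlist(r$counts))
      pv[pb] <- as.integer(unlist(p$counts))
      vec <- abs(pv - rv)
    } else {
      rv[rb] <- 1L; pv[pb] <- 1L
      vec <- switch(mode, concat = c(rv, pv), sum = pmax(rv, pv))
    }
    out[[k]] <- structure(list(scheme = scheme, mode = mode, vector = vec),
                          class = "rxn_fingerprint")
  }
  out
}

#' @export
print.rxn_fingerprint <- function(x, ...) {
  cat("<rxn_fingerprint>", x$scheme, x$mode, "length", length(x$vector),
      "nonzero", sum(x$vector != 0L), "\n")
  invisible(x)
}

#' Tanimoto similarity of two reaction fingerprints
#'
#' Binary vectors use |a AND b| / |a OR b|; count vectors (difference mode)
#' use the generalized form sum(min)/sum(max). Two all-zero vectors are
#' defined as identical (similarity 1).
#'
#' @param a,b \code{rxn_fingerprint} objects with identical scheme and mode.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "rxn_fingerprint"), inherits(b, "rxn_fingerprint"))
  if (a$scheme != b$scheme || a$mode != b$mode) {
    stop("incompatibility error: fingerprints differ in scheme or mode")
  }
  num <- sum(pmin(a$vector, b$vector))
  den <- sum(pmax(a$vector, b$vector))
  if (den == 0) return(1)
  num / den
}

# subset keys used by the search modes; NA components are encoded explicitly
# so that unnamed reactions still form consistent subsets
tight_key <- function(class, name, groups, rings) {
  paste(class, name %||% NA, paste(sort(groups), collapse = "|"),
        paste(sort(rings), collapse = "|"), sep = " :: ")
}

broad_key <- function(class, groups) {
  paste(class, paste(sort(groups), collapse = "|"), sep = " :: ")
}

#' Search a reaction database for similar precedents
#'
#' The candidate subset is chosen by mode: \code{"tight"} requires identical
#' reaction class, name, participating functional groups and participating
#' rings (optionally also the product scaffold); \code{"broad"} requires only
#' class and participating groups; \code{"full"} scans the whole database.
#' Candidates are ranked by Tanimoto similarity of their reaction
#' fingerprints to the query.
#'
#' @param db an annotated \code{rxn_database}.
#' @param analysis an \code{rxn_analysis} of the query (see [analyze()]).
#' @param mode \code{"tight"}, \code{"broad"} or \code{"full"}.
#' @param threshold minimum similarity to report; defaults to 0.9 for MACCS
#'   and 0.6 for ECFP4 fingerprints (the two schemes live on different
#'   similarity scales).
#' @param k maximum number of hits.
#' @param include_scaffold in tight mode, additionally require an identical
#'   product scaffold.
#' @return data.frame of database records with a \code{similarity} column,
#'   sorted by decreasing similarity (ties by record id).
#' @export
search_similar <- function(db, analysis, mode = c("tight", "broad", "full"),
                           threshold = NULL, k = 10L,
                           include_scaffold = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(db, "rxn_database"), inherits(analysis, "rxn_analysis"))
  cfg <- db$config
  if (is.null(threshold)) {
    threshold <- if (cfg$fp_scheme == "maccs") 0.9 else 0.6
  }
  tab <- db$records
  cand <- switch(mode,
    tight = {
      key <- tight_key(analysis$reaction_class, analysis$name,
                       analysis$groups_in_center, analysis$rings_in_center)
      hit <- tab$tight_key == key
      if (include_scaffold) {
        hit <- hit & !is.na(tab$scaffold) &
          tab$scaffold == (analysis$scaffold %||% NA)
      }
      which(hit)
    },
    broad = which(tab$broad_key == broad_key(analysis$reaction_class,
                                             analysis$groups_in_center)),
    full = seq_len(nrow(tab))
  )
  if (!length(cand)) {
    message("no candidate precedents for this ", mode,
            " subset; consider a broader search mode")
    out <- tab[integer(0), , drop = FALSE]
    out$similarity <- numeric(0)
    return(out)
  }
  qfp <- analysis$fingerprint
  if (is.null(qfp) || qfp$scheme != cfg$fp_scheme ||
      qfp$mode != cfg$fp_mode) {
    stop("query fingerprint missing or incompatible with the database ",
         "configuration (", cfg$fp_scheme, "/", cfg$fp_mode, ")")
  }
  sims <- vapply(cand, function(i) tanimoto(qfp, db$fingerprints[[i]]),
                 numeric(1))
  keep <- sims >= threshold
  cand <- cand[keep]; sims <- sims[keep]
  ord <- order(-sims, tab$id[cand])
  cand <- cand[ord][seq_len(min(k, length(cand)))]
  out <- tab[cand, , drop = FALSE]
  out$similarity <- sims[ord][seq_len(length(cand))]
  rownames(out) <- NULL
  out
}
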
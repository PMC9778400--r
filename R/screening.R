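# The ligand-based virtual-screening funnel: similarity enrichment against a
# seed set, canonical-SMILES deduplication, drug-likeness and element
# filters, and activity prediction/ranking with the QSAR model. Every stage
# returns a subset of its input and is free of hidden randomness.

#' Screening configuration
#'
#' @param similarity_threshold retain library molecules whose best Tanimoto
#'   to any seed is strictly greater than this (default 0.8, "greater than
#'   80 percent").
#' @param radius circular-fingerprint radius (default 2, the ECFP4
#'   equivalent).
#' @param nbits fingerprint length.
#' @param qed_min minimum QED (default 0.5).
#' @param mw_max maximum molecular weight in g/mol (default 650).
#' @param element_whitelist allowed element symbols; `NULL` (default) means
#'   the union of elements over the seed set.
#' @param activity_rule candidate flagging rule: `"above_mean_seed"`
#'   (default; see vignette), `"above_max_seed"`, or a numeric pIC50 cutoff.
#' @return a `screening_config` list.
#' @export
screening_config <- function(similarity_threshold = 0.8, radius = 2L,
                             nbits = 2048L, qed_min = 0.5, mw_max = 650,
                             element_whitelist = NULL,
                             activity_rule = "above_mean_seed") {
  stopifnot(similarity_threshold >= 0, similarity_threshold <= 1,
            qed_min >= 0, qed_min <= 1, mw_max > 0)
  if (is.character(activity_rule)) {
    activity_rule <- match.arg(activity_rule,
                               c("above_mean_seed", "above_max_seed"))
  } else {
    stopifnot(is.numeric(activity_rule), length(activity_rule) == 1L)
  }
  structure(list(similarity_threshold = similarity_threshold, radius = radius,
                 nbits = nbits, qed_min = qed_min, mw_max = mw_max,
                 element_whitelist = element_whitelist,
                 activity_rule = activity_rule),
            class = "screening_config")
}

#' Similarity enrichment of a library against seed compounds
#'
#' Keeps library members whose maximum circular-fingerprint Tanimoto
#' similarity to any seed exceeds the configured threshold (strict).
#' Retained rows gain `best_seed_id` and `best_similarity` columns.
#'
#' @param library,seeds `compound_set`s.
#' @param config a [screening_config()].
#' @return the enriched `compound_set`.
#' @export
enrich_by_similarity <- function(library, seeds, config = screening_config()) {
  stopifnot(inherits(library, "compound_set"), inherits(seeds, "compound_set"))
  if (nrow(seeds) == 0L) stop("empty seed set", call. = FALSE)
  seed_fps <- lapply(seeds$smiles, circular_fingerprint,
                     radius = config$radius, nbits = config$nbits)
  best_sim <- numeric(nrow(library))
  best_seed <- character(nrow(library))
  for (k in seq_len(nrow(library))) {
    fp <- circular_fingerprint(library$smiles[k], radius = config$radius,
                               nbits = config$nbits)
    sims <- vapply(seed_fps, tanimoto, 0, b = fp)
    best_sim[k] <- max(sims)
    best_seed[k] <- seeds$id[which.max(sims)]
  }
  # strict ">" per the "greater than 80 percent" rule; threshold 0 disables
  # the filter entirely (otherwise zero-similarity members would still drop)
  keep <- if (config$similarity_threshold == 0) rep(TRUE, nrow(library))
          else best_sim > config$similarity_threshold
  out <- library[keep, , drop = FALSE]
  out$best_seed_id <- best_seed[keep]
  out$best_similarity <- best_sim[keep]
  out
}

#' Deduplicate a compound set by canonical SMILES
#'
#' One record per canonical structure; the first occurrence is kept.
#' Idempotent.
#'
#' @param set a `compound_set`.
#' @return the deduplicated `compound_set`.
#' @export
deduplicate <- function(set) {
  stopifnot(inherits(set, "compound_set"))
  if (nrow(set) == 0L) return(set)
  canon <- vapply(set$smiles, canonicalize, "", USE.NAMES = FALSE)
  set[!duplicated(canon), , drop = FALSE]
}

#' Drug-likeness filter (QED and molecular weight)
#'
#' Keeps compounds with `qed >= qed_min` and `mw <= mw_max`. Rejection
#' counts per reason are attached as the `"rejections"` attribute.
#'
#' @param set a `compound_set`.
#' @param config a [screening_config()].
#' @return the filtered `compound_set` with `qed` and `mw` columns.
#' @export
druglike_filter <- function(set, config = screening_config()) {
  stopifnot(inherits(set, "compound_set"))
  if (nrow(set) == 0L) {
    attr(set, "rejections") <- c(qed = 0L, mw = 0L)
    return(set)
  }
  q <- vapply(set$smiles, qed, 0, USE.NAMES = FALSE)
  w <- vapply(set$smiles, molecular_weight, 0, USE.NAMES = FALSE)
  set$qed <- q
  set$mw <- w
  keep <- q >= config$qed_min & w <= config$mw_max
  out <- set[keep, , drop = FALSE]
  attr(out, "rejections") <- c(qed = sum(q < config$qed_min),
                               mw = sum(w > config$mw_max))
  out
}

#' Element whitelist filter
#'
#' Keeps compounds whose element set is contained in the whitelist (default:
#' the union over the 27-seed reference set, which is C, H, O).
#'
#' @param set a `compound_set`.
#' @param whitelist character vector of allowed element symbols.
#' @return the filtered `compound_set`.
#' @export
element_filter <- function(set, whitelist = c("C", "H", "O")) {
  stopifnot(inherits(set, "compound_set"), length(whitelist) >= 1L)
  if (nrow(set) == 0L) return(set)
  keep <- vapply(set$smiles, function(s) {
    all(element_set(s) %in% whitelist)
  }, FALSE, USE.NAMES = FALSE)
  set[keep, , drop = FALSE]
}

#' Predict, convert and rank screening candidates
#'
#' Predicts pIC50 with the supplied model (descriptors computed natively via
#' [compute_descriptor_vector()] or looked up in a supplied
#' `descriptor_table`), converts to micromolar IC50, sorts by decreasing
#' predicted activity (ties broken by id) and flags candidates passing the
#' activity rule.
#'
#' @param set a `compound_set` surviving the funnel.
#' @param model an `mlr_model` (default: the published 2D equation).
#' @param descriptors optional `descriptor_table` with the model's
#'   descriptors for every compound; when `NULL` they are computed natively.
#' @param seeds the seed `compound_set` (provides the activity threshold).
#' @param config a [screening_config()].
#' @return a data frame of ranked candidates with columns `id`, `smiles`,
#'   `pic50_pre`, `ic50_pre_um`, `passes_threshold` (plus any funnel columns).
#' @export
rank_candidates <- function(set, model = published_model_2d(),
                            descriptors = NULL, seeds = NULL,
                            config = screening_config()) {
  stopifnot(inherits(set, "compound_set"))
  if (nrow(set) == 0L) {
    out <- as.data.frame(set)
    out$pic50_pre <- numeric(0)
    out$ic50_pre_um <- numeric(0)
    out$passes_threshold <- logical(0)
    return(out)
  }
  nm <- names(model$coefficients)
  X <- if (is.null(descriptors)) {
    vals <- t(vapply(set$smiles,
                     function(s) suppressWarnings(compute_descriptor_vector(s)),
                     c(MIC1 = 0, ATS4v = 0, AATS7m = 0, CIC3 = 0,
                       minssCH2 = 0), USE.NAMES = FALSE))
    dimnames(vals) <- list(set$id,
                           c("MIC1", "ATS4v", "AATS7m", "CIC3", "minssCH2"))
    vals
  } else {
    miss <- setdiff(set$id, descriptors$ids)
    if (length(miss)) {
      stop("no descriptors for: ", paste(miss, collapse = ", "), call. = FALSE)
    }
    descriptors$values[set$id, , drop = FALSE]
  }
  bad <- rownames(X)[rowSums(is.na(X[, intersect(nm, colnames(X)), drop = FALSE])) > 0]
  if (length(bad)) {
    stop("missing descriptor values for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pred <- predict(model, X)
  thr <- if (is.numeric(config$activity_rule)) {
    config$activity_rule
  } else {
    if (is.null(seeds) || !("pic50" %in% names(seeds)) ||
        all(is.na(seeds$pic50))) {
      stop("seed pIC50 values required for activity rule '",
           config$activity_rule, "'", call. = FALSE)
    }
    if (config$activity_rule == "above_max_seed") max(seeds$pic50, na.rm = TRUE)
    else mean(seeds$pic50, na.rm = TRUE)
  }
  out <- as.data.frame(set)
  out$pic50_pre <- as.numeric(pred)
  out$ic50_pre_um <- ic50_from_pic50(out$pic50_pre, "micromolar")
  out$passes_threshold <- out$pic50_pre > thr
  out[order(-out$pic50_pre, out$id), , drop = FALSE]
}

#' Run the whole screening funnel
#'
#' enrichment -> deduplication -> drug-likeness -> element filter ->
#' prediction/ranking, with per-stage counts in the `"funnel"` attribute.
#'
#' @inheritParams enrich_by_similarity
#' @inheritParams rank_candidates
#' @return ranked candidate data frame (see [rank_candidates()]).
#' @export
screen_library <- function(library, seeds, model = published_model_2d(),
                           config = screening_config(), descriptors = NULL) {
  wl <- config$element_whitelist %||%
    sort(unique(unlist(lapply(seeds$smiles, element_set))))
  s1 <- enrich_by_similarity(library, seeds, config)
  s2 <- deduplicate(s1)
  s3 <- druglike_filter(s2, config)
  s4 <- element_filter(s3, wl)
  ranked <- rank_candidates(s4, model = model, descriptors = descriptors,
                            seeds = seeds, config = config)
  attr(ranked, "funnel") <- c(library = nrow(library), enriched = nrow(s1),
                              deduplicated = nrow(s2), druglike = nrow(s3),
                              element = nrow(s4))
  ranked
}
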
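#' Rod length after tandem-stagger compression
#'
#' Subtracts per-stagger shortenings from the straight rod length. A tandem
#' stagger at a linker slides the ends of its two flanking coil segments
#' over one another, so the shortening any one stagger can deliver is
#' bounded by the axial length of each flanking segment — and two staggers
#' flanking the *same* segment (as at L12 and L3, which both draw on the
#' short parallel-hendecad region) share that segment's capacity. Staggers
#' are processed in rod order (N- to C-terminal); requested shortenings are
#' truncated to the remaining capacity of their flanking segments.
#'
#' Without a segment map, shortenings are subtracted as given.
#'
#' @param straight_nm Straight (distended) rod length in nm (> 0).
#' @param staggers Data frame with columns `linker` and `shortening_nm`
#'   (requested shortening per stagger, nm), or a numeric vector of
#'   shortenings when `map` is `NULL`.
#' @param map Optional segment map with a `stagger_flanks` attribute
#'   (default [lamin_segment_map()]); pass `NULL` for plain subtraction.
#' @param rise_per_res Rise used to convert flank residue counts to nm.
#' @return One-row tibble: `straight_nm`, `shortening_nm` (total applied),
#'   `length_nm`.
#' @export
rod_shortening <- function(straight_nm, staggers, map = lamin_segment_map(),
                           rise_per_res = 1.485) {
  stopifnot(straight_nm > 0)
  if (is.numeric(staggers)) {
    staggers <- tibble(linker = NA_character_, shortening_nm = staggers)
    map <- NULL
  }
  staggers <- as_tibble(staggers)
  if (nrow(staggers) == 0) {
    return(tibble(straight_nm = straight_nm, shortening_nm = 0,
                  length_nm = straight_nm))
  }
  if (any(staggers$shortening_nm < 0)) abort("stagger shortenings must be >= 0")

  if (is.null(map)) {
    applied <- staggers$shortening_nm
  } else {
    flanks <- attr(map, "stagger_flanks")
    segs <- setNames(
      (map$end - map$start + 1) * rise_per_res / 10,
      map$name
    )
    capacity <- segs
    # process in rod order using the linker anchor order in `flanks`
    ord <- order(match(staggers$linker, names(flanks)))
    applied <- numeric(nrow(staggers))
    for (i in ord) {
      lk <- staggers$linker[i]
      if (!lk %in% names(flanks)) {
        abort(sprintf("unknown stagger linker '%s'", lk))
      }
      fl <- flanks[[lk]]
      eff <- min(staggers$shortening_nm[i], capacity[fl])
      capacity[fl] <- capacity[fl] - eff
      applied[i] <- eff
    }
  }
  total <- sum(applied)
  if (total > straight_nm) {
    abort("total stagger shortening exceeds the straight rod length")
  }
  tibble(straight_nm = straight_nm, shortening_nm = total,
         length_nm = straight_nm - total)
}

# axial overlap (nm) of two fragments: sum of their individual axial
# extents minus the extent of their union, projected on the mean axis
fragment_axial_overlap <- function(model, range_a, range_b, chain = NULL) {
  ca_of <- function(rng) {
    ca <- model[model$elety == "CA" &
                  (if (is.null(chain)) TRUE else model$chain == chain) &
                  model$resno >= min(rng) & model$resno <= max(rng), ,
                drop = FALSE]
    as.matrix(ca[order(ca$resno), c("x", "y", "z")])
  }
  a <- ca_of(range_a); b <- ca_of(range_b)
  axis <- a[nrow(a), ] - a[1, ]
  axis <- axis / sqrt(sum(axis^2))
  pa <- a %*% axis; pb <- b %*% axis
  ext_a <- diff(range(pa)); ext_b <- diff(range(pb))
  ext_union <- diff(range(c(pa, pb)))
  max(ext_a + ext_b - ext_union, 0) / 10
}

#' Screen stagger decoy models against cross-link and geometry criteria
#'
#' Ordered filter pipeline over docked decoy models: (1) imported interface
#' score at or below `score_max` (models without a score pass this step);
#' (2) at least one cross-link satisfied under the chosen mode; (3) the
#' linker-extension cap holds; (4) the two fragments are parallel or close
#' to parallel (angle at most `angle_max`) — only then is the decoy a
#' tandem stagger. The axial overlap of the two fragments is reported as
#' the rod shortening the model conveys.
#'
#' @param models Named list of [coord_model()] tibbles. Each model may
#'   carry attributes `i_sc` (imported docking interface score — never
#'   computed here), `frag_a`/`frag_b` (residue ranges of the two docked
#'   fragments) and `linker` (the linker joining them).
#' @param crosslinks Data frame with `pos_a`, `pos_b` (residue numbers of
#'   candidate cross-links to test).
#' @param map Segment map (default [lamin_segment_map()]).
#' @param mode Cross-link satisfaction mode, `"sas13"` or `"contact4"`.
#' @param score_max Interface-score acceptance cap (default -5).
#' @param angle_max Parallelism threshold in degrees (default 45).
#' @param ... Passed to [crosslink_satisfied()].
#' @return Tibble with one row per model: `model`, `i_sc`, `pass_score`,
#'   `n_satisfied`, `satisfied` (list of cross-link indices), `linker_ok`,
#'   `angle_deg`, `is_tandem_stagger`, `shortening_nm`, `accepted`.
#'   Row order follows the input order; the accepted set does not depend
#'   on it.
#' @export
screen_stagger_decoys <- function(models, crosslinks,
                                  map = lamin_segment_map(),
                                  mode = c("sas13", "contact4"),
                                  score_max = -5, angle_max = 45, ...) {
  mode <- match.arg(mode)
  crosslinks <- as_tibble(crosslinks)
  if (is.null(names(models))) names(models) <- paste0("model_", seq_along(models))
  rows <- purrr::imap(models, function(model, nm) {
    i_sc <- attr(model, "i_sc") %||% NA_real_
    pass_score <- is.na(i_sc) || i_sc <= score_max
    frag_a <- attr(model, "frag_a")
    frag_b <- attr(model, "frag_b")
    linker <- attr(model, "linker")
    sat <- integer(0)
    linker_ok <- NA
    angle <- NA_real_
    shortening <- NA_real_
    if (pass_score) {
      sat <- which(purrr::map_lgl(seq_len(nrow(crosslinks)), function(i) {
        tryCatch(
          crosslink_satisfied(model, crosslinks$pos_a[i], crosslinks$pos_b[i],
                              mode = mode, chain_a = NULL, chain_b = NULL, ...),
          error = function(e) FALSE
        )
      }))
      if (length(sat) > 0) {
        linker_ok <- if (is.null(linker)) TRUE else
          linker_extension_ok(model, linker, map)
        if (isTRUE(linker_ok) && !is.null(frag_a) && !is.null(frag_b)) {
          angle <- helix_pair_angle(model, frag_a, frag_b)
          shortening <- fragment_axial_overlap(model, frag_a, frag_b)
        }
      }
    }
    tibble(
      model = nm, i_sc = i_sc, pass_score = pass_score,
      n_satisfied = length(sat), satisfied = list(sat),
      linker_ok = linker_ok, angle_deg = angle,
      is_tandem_stagger = !is.na(angle) && angle <= angle_max,
      shortening_nm = shortening
    )
  })
  out <- dplyr::bind_rows(rows)
  out$accepted <- out$pass_score & out$n_satisfied > 0 &
    !is.na(out$linker_ok) & out$linker_ok & out$is_tandem_stagger
  out
}
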
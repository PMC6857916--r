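#' Contribution of one term to the linear predictor
#'
#' Evaluates a term's contribution at a value: `beta * x` for covariates, the
#' level's coefficient for factors (zero at the reference), the basis/
#' coefficient dot product for splines, and the product-column contribution
#' for interactions (pass a named list of constituent values).
#'
#' @param model a fitted `dn_model`.
#' @param term a `dn_term` from the model, or its index in `model$terms`.
#' @param value a scalar (covariate/spline), level label (factor), or named
#'   list of constituent values (interaction).
#' @return numeric contribution to eta.
#' @export
term_contribution <- function(model, term, value) {
  idx <- resolve_term(model, term)
  t <- model$terms[[idx]]
  cols <- model$term_columns[[idx]]
  specs <- model$variable_specs
  row <- if (t$kind == "interaction") {
    blocks <- lapply(t$vars, function(v) {
      mt <- model$terms[[main_term_index(model, v)]]
      term_block(mt, one_row_df(v, value[[v]]), specs)
    })
    names(blocks) <- t$vars
    interaction_block(t, blocks)
  } else {
    term_block(t, one_row_df(t$vars, value), specs)
  }
  sum(drop(row) * model$beta[cols])
}

one_row_df <- function(var, value) {
  stats::setNames(data.frame(value, stringsAsFactors = FALSE), var)
}

resolve_term <- function(model, term) {
  if (is.numeric(term)) return(as.integer(term))
  for (i in seq_along(model$terms))
    if (identical(model$terms[[i]][c("kind", "vars", "k", "knots")],
                  term[c("kind", "vars", "k", "knots")])) return(i)
  stop("term not found in model", call. = FALSE)
}

main_term_index <- function(model, var) {
  for (i in seq_along(model$terms)) {
    t <- model$terms[[i]]
    if (t$kind != "interaction" && t$vars == var) return(i)
  }
  stop("no main-effect term for variable '", var, "'", call. = FALSE)
}

# support values over which a term's contribution is evaluated:
# covariate endpoints, all factor levels, a 100-point grid for splines,
# and the cross product of constituent supports for interactions
term_support <- function(model, idx, grid_n = 100L) {
  t <- model$terms[[idx]]
  specs <- model$variable_specs
  sup1 <- function(v, spline = FALSE) {
    s <- specs[[v]]
    if (s$role == "factor") s$levels
    else if (spline) seq(s$observed_min, s$observed_max, length.out = grid_n)
    else c(s$observed_min, s$observed_max)
  }
  if (t$kind == "interaction") {
    spline_vars <- unlist(lapply(model$terms, function(u)
      if (u$kind == "spline") u$vars))
    grids <- lapply(t$vars, function(v) sup1(v, v %in% spline_vars))
    names(grids) <- t$vars
    expand.grid(grids, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  } else {
    sup1(t$vars, t$kind == "spline")
  }
}

term_span <- function(model, idx, grid_n = 100L) {
  sup <- term_support(model, idx, grid_n)
  vals <- if (is.data.frame(sup)) {
    vapply(seq_len(nrow(sup)), function(r)
      term_contribution(model, idx, as.list(sup[r, , drop = FALSE])),
      numeric(1))
  } else {
    vapply(sup, function(v) term_contribution(model, idx, v), numeric(1))
  }
  c(min(vals), max(vals))
}

#' Relative ruler length of a term
#'
#' The span of the term's contribution over its observed support, divided by
#' the largest such span across all model terms; the dominant term has length
#' exactly 1. For linear covariates this is `range(x) * |beta| /
#' max_i(range(x_i) * |beta_i|)`; factors use all levels and splines a
#' 100-point grid, so the definition extends to non-linear terms.
#'
#' @param model a fitted `dn_model`.
#' @param term a `dn_term` or term index.
#' @return length in `[0, 1]`; a zero-span term returns 0 with a warning.
#' @export
ruler_length <- function(model, term) {
  idx <- resolve_term(model, term)
  spans <- vapply(seq_along(model$terms), function(i)
    diff(term_span(model, i)), numeric(1))
  if (spans[idx] == 0) {
    warning("term '", term_label(model$terms[[idx]]),
            "' has zero contribution span", call. = FALSE)
    return(0)
  }
  spans[idx] / max(spans)
}

# partition terms into axis groups: variables joined by an interaction share
# a group, whose axes are stratified by the factor levels involved
axis_groups <- function(model) {
  vars <- formula_vars(model$formula)
  parent <- stats::setNames(seq_along(vars), vars)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (t in model$terms) if (t$kind == "interaction") {
    r <- find(match(t$vars[1], vars))
    for (v in t$vars[-1]) parent[find(match(v, vars))] <- r
  }
  comp <- vapply(seq_along(vars), find, numeric(1))
  lapply(unique(comp), function(cid) {
    gv <- vars[comp == cid]
    idx <- which(vapply(model$terms, function(t) all(t$vars %in% gv), logical(1)))
    list(vars = gv, term_idx = idx)
  })
}

group_contribution <- function(model, group, values) {
  sum(vapply(group$term_idx, function(i) {
    t <- model$terms[[i]]
    if (t$kind == "interaction")
      term_contribution(model, i, values[t$vars])
    else
      term_contribution(model, i, values[[t$vars]])
  }, numeric(1)))
}

#' Build the static nomogram geometry
#'
#' Constructs per-term point rulers (the dominant term spanning exactly 100
#' points and the others scaled by their relative contribution span), the
#' total-points range, and the mapping from total points through the linear
#' predictor to the response scale. Interactions that involve at least one
#' factor produce stratified axes (one ruler of the covariate per
#' factor-level combination, main effects folded in); interactions between
#' two covariates, or involving a spline, have no faithful static ruler and
#' are refused in favour of the dynamic interface.
#'
#' @param model a fitted `dn_model`.
#' @param grid_n evaluation grid size for spline axes.
#' @param n_response_ticks target number of "nice" response-axis ticks.
#' @return an object of class `dn_layout`.
#' @export
build_layout <- function(model, grid_n = 100L, n_response_ticks = 7L) {
  specs <- model$variable_specs
  spline_vars <- unlist(lapply(model$terms, function(t)
    if (t$kind == "spline") t$vars))
  groups <- axis_groups(model)

  for (g in groups) {
    has_int <- any(vapply(g$term_idx, function(i)
      model$terms[[i]]$kind == "interaction", logical(1)))
    if (!has_int) next
    numeric_vars <- g$vars[vapply(g$vars, function(v)
      specs[[v]]$role == "covariate", logical(1))]
    if (length(intersect(g$vars, spline_vars)))
      stop("static layout does not support interactions involving a spline; ",
           "use the dynamic interface", call. = FALSE)
    if (length(numeric_vars) > 1L)
      stop("static layout does not support covariate-by-covariate ",
           "interactions; use the dynamic interface", call. = FALSE)
  }

  # per-group axes, spans and offsets
  group_info <- lapply(groups, function(g) {
    has_int <- any(vapply(g$term_idx, function(i)
      model$terms[[i]]$kind == "interaction", logical(1)))
    fvars <- g$vars[vapply(g$vars, function(v)
      specs[[v]]$role == "factor", logical(1))]
    nvar <- setdiff(g$vars, fvars)

    if (!has_int) {
      i <- g$term_idx[1L]
      t <- model$terms[[i]]
      if (t$kind == "factor") {
        sup <- specs[[t$vars]]$levels
        contrib <- vapply(sup, function(l) term_contribution(model, i, l),
                          numeric(1))
        axes <- list(list(label = t$vars, stratum = NULL, kind = "factor",
                          values = sup, contributions = contrib))
      } else {
        s <- specs[[t$vars]]
        xg <- seq(s$observed_min, s$observed_max, length.out = grid_n)
        contrib <- vapply(xg, function(x) term_contribution(model, i, x),
                          numeric(1))
        axes <- list(list(label = term_label(t), stratum = NULL,
                          kind = t$kind, values = xg, contributions = contrib))
      }
    } else if (length(nvar) == 1L) {
      s <- specs[[nvar]]
      xg <- seq(s$observed_min, s$observed_max, length.out = grid_n)
      strata <- expand.grid(lapply(fvars, function(v) specs[[v]]$levels),
                            stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
      names(strata) <- fvars
      axes <- lapply(seq_len(nrow(strata)), function(r) {
        lv <- as.list(strata[r, , drop = FALSE])
        contrib <- vapply(xg, function(x)
          group_contribution(model, g, c(stats::setNames(list(x), nvar), lv)),
          numeric(1))
        list(label = sprintf("%s (%s)", nvar,
                             paste(fvars, unlist(lv), sep = "=", collapse = ", ")),
             stratum = stats::setNames(unlist(lv), fvars), kind = "covariate",
             values = xg, contributions = contrib)
      })
    } else {
      # factors only: one categorical axis over the level combinations
      combos <- expand.grid(lapply(fvars, function(v) specs[[v]]$levels),
                            stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
      names(combos) <- fvars
      labs <- apply(combos, 1L, function(r)
        paste(fvars, r, sep = "=", collapse = ", "))
      contrib <- vapply(seq_len(nrow(combos)), function(r)
        group_contribution(model, g, as.list(combos[r, , drop = FALSE])),
        numeric(1))
      axes <- list(list(label = paste(fvars, collapse = " x "), stratum = NULL,
                        kind = "factor", values = labs, contributions = contrib))
    }
    all_contrib <- unlist(lapply(axes, `[[`, "contributions"))
    list(group = g, axes = axes, min = min(all_contrib),
         span = max(all_contrib) - min(all_contrib))
  })

  spans <- vapply(group_info, `[[`, numeric(1), "span")
  if (all(spans == 0)) stop("all terms have zero contribution span", call. = FALSE)
  max_span <- max(spans)
  ppu <- 100 / max_span  # points per unit of linear predictor

  axes <- list()
  for (gi in group_info) {
    for (ax in gi$axes) {
      pts <- (ax$contributions - gi$min) * ppu
      ticks <- axis_ticks(ax, pts)
      axes[[length(axes) + 1L]] <- list(
        label = ax$label, stratum = ax$stratum, kind = ax$kind,
        max_points = gi$span * ppu, ticks = ticks,
        contribution_grid = if (ax$kind %in% c("covariate", "spline"))
          data.frame(x = ax$values, contribution = ax$contributions,
                     points = pts))
    }
  }

  offset_sum <- sum(vapply(group_info, `[[`, numeric(1), "min"))
  base_eta <- offset_sum +
    if (model$has_intercept) unname(model$beta[1L])
    else if (inherits(model, "dn_cox"))
      -sum(model$covariate_means * model$beta)  # contributions are uncentered
    else 0
  total_max <- sum(vapply(group_info, `[[`, numeric(1), "span")) * ppu

  layout <- structure(list(
    axes = axes, points_per_unit_eta = ppu,
    total_points_range = c(0, total_max), base_eta = base_eta,
    family = model$family, link = model$link,
    groups = lapply(group_info, function(gi)
      list(vars = gi$group$vars, term_idx = gi$group$term_idx, min = gi$min,
           span = gi$span))),
    class = "dn_layout")
  layout$response_ticks <- response_ticks(layout, n_response_ticks)
  layout
}

axis_ticks <- function(ax, pts) {
  if (ax$kind == "factor") {
    return(data.frame(value = as.character(ax$values), points = pts,
                      stringsAsFactors = FALSE))
  }
  xg <- ax$values
  cand <- pretty(range(xg), 5)
  cand <- cand[cand >= min(xg) & cand <= max(xg)]
  # guarantee ticks at the contribution extremes (0 points and the axis max)
  cand <- sort(unique(c(cand, xg[which.min(pts)], xg[which.max(pts)])))
  p_at <- stats::approx(xg, pts, xout = cand)$y
  data.frame(value = format(cand, trim = TRUE, digits = 6),
             x = cand, points = p_at, stringsAsFactors = FALSE)
}

# map total points -> linear predictor -> response scale
eta_from_points <- function(layout, total_points) {
  layout$base_eta + total_points / layout$points_per_unit_eta
}

response_from_points <- function(layout, total_points) {
  eta <- eta_from_points(layout, total_points)
  if (layout$family == "cox") exp(eta)
  else family_info(layout$family, layout$link)$linkinv(eta)
}

response_ticks <- function(layout, n = 7L) {
  tp <- layout$total_points_range
  ends <- response_from_points(layout, tp)
  if (layout$family == "gamma") {
    # reciprocal link: undefined where eta crosses 0; restrict to one branch
    etas <- eta_from_points(layout, tp)
    if (prod(etas) <= 0) return(data.frame(points = numeric(0),
                                           response = numeric(0)))
  }
  cand <- pretty(sort(ends), n)
  cand <- cand[cand >= min(ends) & cand <= max(ends)]
  linkfun <- if (layout$family == "cox") log
    else family_info(layout$family, layout$link)$linkfun
  ok <- if (layout$family %in% c("binomial")) cand > 0 & cand < 1
        else if (layout$family %in% c("poisson", "cox", "gamma")) cand > 0
        else rep(TRUE, length(cand))
  cand <- cand[ok]
  pts <- (linkfun(cand) - layout$base_eta) * layout$points_per_unit_eta
  keep <- pts >= tp[1] - 1e-9 & pts <= tp[2] + 1e-9
  data.frame(points = pts[keep], response = cand[keep])
}

#' Total points for an input under a layout
#'
#' Sums the per-axis points a reader would tally for the given input and
#' returns them together with the implied response estimate. This is the
#' graphical-calculation path; it must agree with [predict_response()].
#'
#' @param layout a [build_layout()] result.
#' @param model the model the layout was built from.
#' @param x_new named list of input values.
#' @return list with `axis_points`, `total`, `eta`, `response`.
#' @export
total_points <- function(layout, model, x_new) {
  pts <- vapply(layout$groups, function(g) {
    vals <- x_new[g$vars]
    (group_contribution(model, list(vars = g$vars, term_idx = g$term_idx),
                        vals) - g$min) * layout$points_per_unit_eta
  }, numeric(1))
  tot <- sum(pts)
  list(axis_points = pts, total = tot,
       eta = eta_from_points(layout, tot),
       response = response_from_points(layout, tot))
}

#' @export
print.dn_layout <- function(x, ...) {
  cat(sprintf("<nomogram layout> %d axes, total points 0..%.1f\n",
              length(x$axes), x$total_points_range[2]))
  for (ax in x$axes)
    cat(sprintf("  %-28s 0..%.1f points\n", ax$label, ax$max_points))
  invisible(x)
}

#' Layout as a plain list (JSON-ready)
#'
#' @param layout a [build_layout()] result.
#' @param path optional output file for JSON.
#' @return the list, or `path` invisibly when written.
#' @export
layout_json <- function(layout, path = NULL) {
  obj <- list(
    points_per_unit_eta = layout$points_per_unit_eta,
    total_points_range = layout$total_points_range,
    base_eta = layout$base_eta, family = layout$family, link = layout$link,
    axes = lapply(layout$axes, function(ax) list(
      label = ax$label, kind = ax$kind,
      stratum = if (!is.null(ax$stratum)) as.list(ax$stratum),
      max_points = ax$max_points,
      ticks = ax$ticks,
      contribution_grid = ax$contribution_grid)),
    response_ticks = layout$response_ticks)
  if (is.null(path)) return(obj)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(10),
                       dataframe = "columns")
  invisible(path)
}
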
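#' Shipped formation templates
#'
#' Role-box rectangles for the three offered formations (3-5-2, 4-4-2,
#' 4-3-3), expressed for a team defending the `-x` goal and attacking `+x`.
#' The extents are modelling assumptions (goalkeeper box spanning the penalty
#' area; defender, midfielder and forward bands covering overlapping thirds of
#' the pitch); they are deliberately editable — see
#' `system.file("extdata", "formations.csv", package = "kickmod")` for the
#' plain-text version and [read_formation_templates()] to load a modified one.
#'
#' @return A tibble with columns `formation, slot, role, xmin, ymin, xmax,
#'   ymax`; 11 rows (slots 1-11) per formation. Slot 1 is always the
#'   goalkeeper.
#' @examples
#' formation_templates() %>% dplyr::count(formation)
#' @export
formation_templates <- function() {
  tpl <- list(
    "3-5-2" = list(
      list("G",   -55.0, -20.0, -38.5, 20.0),
      list("lCB", -52.0,   2.0, -15.0, 28.0),
      list("CB",  -52.0, -13.0, -15.0, 13.0),
      list("rCB", -52.0, -28.0, -15.0, -2.0),
      list("lB",  -45.0,  14.0,  25.0, 30.0),
      list("lMF", -35.0,   0.0,  20.0, 22.0),
      list("CMF", -35.0, -11.0,  20.0, 11.0),
      list("rMF", -35.0, -22.0,  20.0,  0.0),
      list("rB",  -45.0, -30.0,  25.0, -14.0),
      list("lF",  -15.0,  -2.0,  52.0, 24.0),
      list("rF",  -15.0, -24.0,  52.0,  2.0)
    ),
    "4-4-2" = list(
      list("G",    -55.0, -20.0, -38.5, 20.0),
      list("lB",   -52.0,  16.0,   0.0, 30.0),
      list("lCB",  -52.0,   1.0, -10.0, 18.0),
      list("rCB",  -52.0, -18.0, -10.0, -1.0),
      list("rB",   -52.0, -30.0,   0.0, -16.0),
      list("lMF",  -30.0,  12.0,  25.0, 30.0),
      list("lCMF", -30.0,  -2.0,  20.0, 16.0),
      list("rCMF", -30.0, -16.0,  20.0,  2.0),
      list("rMF",  -30.0, -30.0,  25.0, -12.0),
      list("lF",   -10.0,   0.0,  52.0, 24.0),
      list("rF",   -10.0, -24.0,  52.0,  0.0)
    ),
    # slot order matches the published id->role examples for this formation
    # (slot 3 = lB, slot 7 = rMF, slot 9 = CF)
    "4-3-3" = list(
      list("G",   -55.0, -20.0, -38.5, 20.0),
      list("rB",  -52.0, -30.0,   0.0, -16.0),
      list("lB",  -52.0,  16.0,   0.0, 30.0),
      list("rCB", -52.0, -18.0, -10.0, -1.0),
      list("lCB", -52.0,   1.0, -10.0, 18.0),
      list("CMF", -32.0, -11.0,  18.0, 11.0),
      list("rMF", -32.0, -26.0,  18.0, -4.0),
      list("lMF", -32.0,   4.0,  18.0, 26.0),
      list("CF",  -12.0, -11.0,  52.0, 11.0),
      list("rF",  -12.0, -30.0,  52.0, -8.0),
      list("lF",  -12.0,  -8.0,  52.0, 30.0)
    )
  )
  purrr::map_dfr(names(tpl), function(fn) {
    purrr::map_dfr(seq_along(tpl[[fn]]), function(i) {
      r <- tpl[[fn]][[i]]
      tibble(formation = fn, slot = i, role = r[[1]],
             xmin = r[[2]], ymin = r[[3]], xmax = r[[4]], ymax = r[[5]])
    })
  })
}

#' Read formation templates from a plain-text file
#'
#' The file must be a delimited table with columns
#' `formation, slot, role, xmin, ymin, xmax, ymax` (one rectangle per role),
#' in pitch coordinates for a team defending the `-x` goal.
#'
#' @param path Path to a CSV file.
#' @return A tibble in the [formation_templates()] layout.
#' @export
read_formation_templates <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("formation", "slot", "role", "xmin", "ymin", "xmax", "ymax")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("formation file is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "kickmod_parse_error")
  }
  as_tibble(df[need])
}

#' Build a team's formation
#'
#' Instantiates the 11 role boxes of a named formation for one side. Side A
#' defends the `-x` goal, so its boxes are the templates verbatim; side B's
#' boxes are the point reflection of side A's through the pitch centre.
#'
#' @param name Formation name: one of `"3-5-2"`, `"4-4-2"`, `"4-3-3"`.
#' @param side `"A"` or `"B"`.
#' @param pitch A [pitch_config()].
#' @param templates Template table as returned by [formation_templates()].
#' @return An object of class `formation`: a list with `name`, `side`, and
#'   `boxes`, a list of 11 [role_box()] objects ordered by slot.
#' @examples
#' f <- build_formation("3-5-2", "A")
#' length(f$boxes)
#' @export
build_formation <- function(name, side = c("A", "B"), pitch = pitch_config(),
                            templates = formation_templates()) {
  side <- match.arg(side)
  rows <- templates[templates$formation == name, , drop = FALSE]
  if (nrow(rows) == 0) {
    abort(paste0("unknown formation '", name,
                 "'; offered options are 3-5-2, 4-4-2, 4-3-3"),
          class = "kickmod_formation_error")
  }
  if (nrow(rows) != 11) {
    abort(paste0("formation '", name, "' must have exactly 11 role boxes"),
          class = "kickmod_formation_error")
  }
  if (sum(rows$role == "G") != 1) {
    abort(paste0("formation '", name, "' must have exactly one goalkeeper"),
          class = "kickmod_formation_error")
  }
  rows <- rows[order(rows$slot), , drop = FALSE]
  boxes <- purrr::pmap(rows, function(formation, slot, role,
                                      xmin, ymin, xmax, ymax) {
    if (side == "B") {
      # point reflection through the origin swaps and negates both corners
      b <- role_box(role, -xmax, -ymax, -xmin, -ymin)
    } else {
      b <- role_box(role, xmin, ymin, xmax, ymax)
    }
    if (b$xmin < -pitch$xmax || b$xmax > pitch$xmax ||
        b$ymin < -pitch$ymax || b$ymax > pitch$ymax) {
      abort(paste0("role box '", role, "' lies outside the pitch"),
            class = "kickmod_formation_error")
    }
    b
  })
  structure(list(name = name, side = side, boxes = boxes),
            class = "formation")
}

#' @export
print.formation <- function(x, ...) {
  cat("<formation ", x$name, ", side ", x$side, ">\n", sep = "")
  for (i in seq_along(x$boxes)) {
    b <- x$boxes[[i]]
    cat(sprintf("  %2d %-4s [%6.1f, %6.1f] x [%6.1f, %6.1f]\n",
                i, b$role, b$xmin, b$xmax, b$ymin, b$ymax))
  }
  invisible(x)
}
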
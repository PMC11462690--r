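# Vector rendering of logo figures.
#
# A figure is first assembled into a "scene": a flat list of primitives
# (rects, lines, text, letter glyphs) in final figure coordinates (y down,
# as in SVG). The scene is then serialised to SVG by a deterministic writer
# (fixed number formatting, sequential ids; identical inputs give
# byte-identical files) or replayed onto a grDevices pdf()/png() device.
# Every data-carrying element records its source value in data-* attributes
# and its geometry in plain coordinates, so figures are machine-checkable.

#' Rendering configuration
#'
#' @param format Output format: `"svg"` (primary, structure-tested),
#'   `"pdf"` or `"png"`.
#' @param col_width Column width in px.
#' @param px_per_bit Vertical scale in px per bit.
#' @param base_colors Named fill colors for A, C, G, T.
#' @param meth_colors Named fill colors for the six methylation components
#'   `CG+ CHG+ CHH+ CG- CHG- CHH-` (must be distinct).
#' @param shade_color Fill of the methylation shading overlay on C/G glyphs.
#' @param dash SVG dash pattern for expected-methylation and bound lines.
#' @param font_size Base font size in px.
#' @param title Figure title (e.g. TF and cell line).
#' @param label Background label shown in the key (e.g. `"WG"` or `"PR"`).
#' @param show_axes Draw axis labels and tick text.
#' @return A `render_config` object.
#' @export
render_config <- function(format = "svg",
                          col_width = 36,
                          px_per_bit = 40,
                          base_colors = c(
                            A = "#109648", C = "#255C99",
                            G = "#F7B32B", T = "#D62839"
                          ),
                          meth_colors = c(
                            "CG+" = "#1B7837", "CHG+" = "#762A83",
                            "CHH+" = "#2166AC", "CG-" = "#A6DBA0",
                            "CHG-" = "#C2A5CF", "CHH-" = "#92C5DE"
                          ),
                          shade_color = "#3C3C3C",
                          dash = "5,3",
                          font_size = 11,
                          title = "",
                          label = "WG",
                          show_axes = TRUE) {
  format <- match.arg(format, c("svg", "pdf", "png"))
  if (anyDuplicated(meth_colors)) stop("methylation component colors must be distinct")
  structure(
    list(
      format = format, col_width = col_width, px_per_bit = px_per_bit,
      base_colors = base_colors, meth_colors = meth_colors,
      shade_color = shade_color, dash = dash, font_size = font_size,
      title = title, label = label, show_axes = show_axes
    ),
    class = "render_config"
  )
}

# ---- letter glyphs ---------------------------------------------------------
# Unit-box outlines (x, y in [0,1], y down, baseline at y = 1), defined as
# polygon subpaths; no font dependency, so geometry is exact on every device.

ring_points <- function(a0, a1, r, steps = 20L) {
  ang <- seq(a0, a1, length.out = steps) * pi / 180
  cbind(round(0.5 + r * cos(ang), 4L), round(0.5 - r * sin(ang), 4L))
}

letter_paths <- local({
  A <- list(
    subpaths = list(
      cbind(
        c(0, 0.4, 0.6, 1, 0.82, 0.72, 0.28, 0.18),
        c(1, 0, 0, 1, 1, 0.76, 0.76, 1)
      ),
      cbind(c(0.5, 0.655, 0.345), c(0.2, 0.6, 0.6))
    ),
    rule = "evenodd"
  )
  Cc <- list(
    subpaths = list(
      rbind(ring_points(40, 320, 0.5), ring_points(320, 40, 0.3))
    ),
    rule = "nonzero"
  )
  G <- list(
    subpaths = list(
      rbind(ring_points(35, 325, 0.5), ring_points(325, 35, 0.3)),
      cbind(c(0.55, 1.0, 1.0, 0.82, 0.82, 0.55), c(0.48, 0.48, 0.95, 0.95, 0.62, 0.62))
    ),
    rule = "nonzero"
  )
  T <- list(
    subpaths = list(
      cbind(
        c(0, 1, 1, 0.6, 0.6, 0.4, 0.4, 0),
        c(0, 0, 0.16, 0.16, 1, 1, 0.16, 0.16)
      )
    ),
    rule = "nonzero"
  )
  list(A = A, C = Cc, G = G, T = T)
})

letter_path_d <- function(base) {
  lp <- letter_paths[[base]]
  paste(vapply(lp$subpaths, function(m) {
    paste0(
      "M", m[1L, 1L], ",", m[1L, 2L], " ",
      paste0("L", m[-1L, 1L], ",", m[-1L, 2L], collapse = " "), " Z"
    )
  }, character(1L)), collapse = " ")
}

# ---- scene primitives ------------------------------------------------------

prim_rect <- function(x, y, w, h, fill, stroke = NA, opacity = NA, data = NULL) {
  list(kind = "rect", x = x, y = y, w = w, h = h, fill = fill, stroke = stroke, opacity = opacity, data = data)
}
prim_line <- function(x1, y1, x2, y2, stroke = "#000000", dash = NA, lwd = 1, data = NULL) {
  list(kind = "line", x1 = x1, y1 = y1, x2 = x2, y2 = y2, stroke = stroke, dash = dash, lwd = lwd, data = data)
}
prim_polyline <- function(x, y, stroke, lwd = 1.5, data = NULL) {
  list(kind = "polyline", x = x, y = y, stroke = stroke, lwd = lwd, data = data)
}
prim_text <- function(x, y, str, size, anchor = "start", fill = "#000000", data = NULL) {
  list(kind = "text", x = x, y = y, str = str, size = size, anchor = anchor, fill = fill, data = data)
}
prim_glyph <- function(base, x, y, w, h, fill, shade = NA, expected = NA,
                       shade_fill = "#3C3C3C", dash = "5,3", data = NULL) {
  list(
    kind = "glyph", base = base, x = x, y = y, w = w, h = h, fill = fill,
    shade = shade, expected = expected, shade_fill = shade_fill, dash = dash,
    data = data
  )
}

scene <- function(width, height, prims) {
  list(width = width, height = height, prims = prims)
}

# ---- logo scene ------------------------------------------------------------

build_logo_scene <- function(tracks, motif, mbg, bg0, cfg = render_config()) {
  stopifnot(inherits(tracks, "track_set"))
  L <- tracks$L
  if (L < 1L) stop("zero-length motif")
  cw <- cfg$col_width
  ppb <- cfg$px_per_bit
  fs <- cfg$font_size
  ml <- 48
  key_w <- 140
  mr <- key_w + 16
  mt <- if (nzchar(cfg$title)) 26 else 10
  gap <- 20

  plus_cols <- paste0(CONTEXTS, "+")
  minus_cols <- paste0(CONTEXTS, "-")
  meth_up <- max(rowSums(tracks$meth[, plus_cols, drop = FALSE]), 0.05)
  meth_dn <- max(rowSums(tracks$meth[, minus_cols, drop = FALSE]), 0.05)
  seq_max <- max(tracks$seq_heights, 1)
  dim_up <- max(tracks$dimer_bound_max, 0) + 0.05
  dim_dn <- max(-min(tracks$dimer_bound_min, 0), 0.05)

  y_meth0 <- mt + meth_up * ppb # methylation track baseline
  y_seq_top <- y_meth0 + meth_dn * ppb + gap
  y_seq0 <- y_seq_top + seq_max * ppb # sequence baseline
  y_dim0 <- y_seq0 + gap + dim_up * ppb # dimer zero line
  height <- y_dim0 + dim_dn * ppb + 26
  width <- ml + L * cw + mr
  colx <- function(i) ml + (i - 1L) * cw # left edge of column i (1-based)

  p <- list()
  add <- function(x) p[[length(p) + 1L]] <<- x

  if (nzchar(cfg$title)) {
    add(prim_text(ml, mt - 10, cfg$title, fs + 3, data = c("data-role" = "title")))
  }

  # --- methylation track (top): + components up, - components down ---------
  add(prim_line(ml, y_meth0, ml + L * cw, y_meth0,
    data = c("data-role" = "meth-axis")
  ))
  for (i in seq_len(L)) {
    y <- y_meth0
    for (cn in plus_cols) {
      v <- tracks$meth[i, cn]
      if (v > 0) {
        h <- v * ppb
        add(prim_rect(colx(i) + 2, y - h, cw - 4, h, cfg$meth_colors[[cn]],
          data = c(
            "data-role" = "meth-seg", "data-col" = i - 1L,
            "data-ctx" = substr(cn, 1L, nchar(cn) - 1L),
            "data-strand" = "+", "data-bits" = fmt_data(v)
          )
        ))
        y <- y - h
      }
    }
    y <- y_meth0
    for (cn in minus_cols) {
      v <- tracks$meth[i, cn]
      if (v > 0) {
        h <- v * ppb
        add(prim_rect(colx(i) + 2, y, cw - 4, h, cfg$meth_colors[[cn]],
          data = c(
            "data-role" = "meth-seg", "data-col" = i - 1L,
            "data-ctx" = substr(cn, 1L, nchar(cn) - 1L),
            "data-strand" = "-", "data-bits" = fmt_data(v)
          )
        ))
        y <- y + h
      }
    }
  }
  if (cfg$show_axes) {
    add(prim_text(ml - 6, y_meth0 - meth_up * ppb + fs, fmt_axis(meth_up), fs - 2,
      anchor = "end"
    ))
    add(prim_text(ml - 6, y_meth0 + 3, "0", fs - 2, anchor = "end"))
    add(prim_text(10, y_meth0 - 6, "methylation (bits)", fs - 2,
      data = c("data-role" = "track-label")
    ))
  }

  # --- sequence track (middle): stacked letters, largest on top ------------
  for (i in seq_len(L)) {
    hts <- tracks$letters[i, ]
    ord <- order(hts) # ascending: smallest nearest the baseline
    y <- y_seq0
    for (b in BASES[ord]) {
      hb <- tracks$letters[i, b]
      if (hb <= 0) next
      h <- hb * ppb
      shade <- NA_real_
      expected <- NA_real_
      if (b == "C") {
        shade <- tracks$observed[i, "+"]
        expected <- tracks$expected[i, "+"]
      } else if (b == "G") {
        shade <- tracks$observed[i, "-"]
        expected <- tracks$expected[i, "-"]
      }
      add(prim_glyph(b, colx(i) + 1, y - h, cw - 2, h, cfg$base_colors[[b]],
        shade = shade, expected = expected, shade_fill = cfg$shade_color,
        dash = cfg$dash,
        data = c(
          "data-role" = "seq-glyph", "data-col" = i - 1L,
          "data-base" = b, "data-bits" = fmt_data(hb)
        )
      ))
      y <- y - h
    }
  }
  add(prim_line(ml, y_seq0, ml + L * cw, y_seq0, data = c("data-role" = "seq-axis")))
  if (cfg$show_axes) {
    add(prim_text(ml - 6, y_seq_top + fs, fmt_axis(seq_max), fs - 2, anchor = "end"))
    add(prim_text(ml - 6, y_seq0 + 3, "0", fs - 2, anchor = "end"))
    add(prim_text(10, y_seq_top + fs, "sequence (bits)", fs - 2,
      data = c("data-role" = "track-label")
    ))
    for (i in seq_len(L)) {
      add(prim_text(colx(i) + cw / 2, y_seq0 + fs + 2, as.character(i), fs - 2,
        anchor = "middle"
      ))
    }
  }

  # --- dimer track (bottom): bars between adjacent columns -----------------
  add(prim_line(ml, y_dim0, ml + L * cw, y_dim0, data = c("data-role" = "dimer-axis")))
  for (v in c(tracks$dimer_bound_max, tracks$dimer_bound_min)) {
    add(prim_line(ml, y_dim0 - v * ppb, ml + L * cw, y_dim0 - v * ppb,
      stroke = "#888888", dash = cfg$dash,
      data = c("data-role" = "dimer-bound", "data-bits" = fmt_data(v))
    ))
  }
  if (L >= 2L) {
    for (j in seq_len(L - 1L)) {
      v <- tracks$dimer_heights[j]
      h <- abs(v) * ppb
      if (h == 0) next
      xc <- ml + j * cw # boundary between columns j and j+1
      ytop <- if (v >= 0) y_dim0 - h else y_dim0
      add(prim_rect(xc - cw / 4, ytop, cw / 2, h, "#6A6A6A",
        data = c(
          "data-role" = "dimer-bar", "data-step" = j - 1L,
          "data-bits" = fmt_data(v)
        )
      ))
    }
  }
  if (cfg$show_axes) {
    add(prim_text(10, y_dim0 - dim_up * ppb + fs, "dimer (bits)", fs - 2,
      data = c("data-role" = "track-label")
    ))
    add(prim_text(ml - 6, y_dim0 + 3, "0", fs - 2, anchor = "end"))
  }

  # --- key box (lower right) ----------------------------------------------
  kb_x <- ml + L * cw + 12
  kb_y <- y_seq_top
  kb_h <- 9 * (fs + 3)
  add(prim_rect(kb_x, kb_y, key_w, kb_h, "#FFFFFF",
    stroke = "#000000",
    data = c("data-role" = "key-box")
  ))
  ky <- kb_y + fs + 3
  add(prim_text(kb_x + 6, ky, paste0("background: ", cfg$label), fs - 1))
  for (cx in CONTEXTS) {
    ky <- ky + fs + 3
    add(prim_text(kb_x + 6, ky, sprintf("m%s %.3f", cx, mbg$m[[cx]]), fs - 1,
      data = c("data-role" = "key-meth", "data-ctx" = cx, "data-value" = fmt_data(mbg$m[[cx]]))
    ))
  }
  for (b in BASES) {
    ky <- ky + fs + 3
    add(prim_text(kb_x + 6, ky, sprintf("q(%s) %.3f", b, bg0$q[[b]]), fs - 1,
      fill = cfg$base_colors[[b]],
      data = c("data-role" = "key-base", "data-base" = b, "data-value" = fmt_data(bg0$q[[b]]))
    ))
  }

  scene(width, height, p)
}

fmt_data <- function(x) sprintf("%.12g", x)
fmt_axis <- function(x) sub("\\.?0+$", "", sprintf("%.2f", x))

# ---- flanking-profile scene ------------------------------------------------

build_scape_scene <- function(profile, cfg = render_config()) {
  stopifnot(inherits(profile, "scape_profile"))
  fs <- cfg$font_size
  pw <- 180 # panel width
  ph <- 90 # panel height
  ml <- 52
  mt <- if (nzchar(cfg$title)) 30 else 14
  gx <- 26
  gy <- 26
  offs <- profile$offsets
  xr <- range(offs)
  emax <- max(profile$e, 1e-3)
  rows <- c("entropy", "methylation", "context")
  width <- ml + 3 * pw + 2 * gx + 16
  height <- mt + 3 * ph + 2 * gy + 36

  p <- list()
  add <- function(x) p[[length(p) + 1L]] <<- x
  if (nzchar(cfg$title)) {
    add(prim_text(ml, mt - 12, cfg$title, fs + 3, data = c("data-role" = "title")))
  }
  sx <- function(o, px0) px0 + (o - xr[1L]) / (xr[2L] - xr[1L]) * pw
  for (ci in seq_along(CONTEXTS)) {
    cx <- CONTEXTS[ci]
    px0 <- ml + (ci - 1L) * (pw + gx)
    add(prim_text(px0 + pw / 2, mt - 2, c(CG = "CpG", CHG = "CHG", CHH = "CHH")[[cx]],
      fs,
      anchor = "middle", data = c("data-role" = "panel-title", "data-ctx" = cx)
    ))
    for (ri in seq_along(rows)) {
      py0 <- mt + (ri - 1L) * (ph + gy) # panel top
      ymax <- if (rows[ri] == "entropy") emax else 1
      vals <- switch(rows[ri],
        entropy = profile$e[, cx],
        methylation = profile$m[, cx],
        context = profile$P[, cx]
      )
      # panel frame and motif span
      add(prim_rect(px0, py0, pw, ph, "none",
        stroke = "#444444",
        data = c("data-role" = "panel", "data-ctx" = cx, "data-row" = rows[ri])
      ))
      add(prim_rect(sx(0, px0), py0, sx(profile$L - 1L, px0) - sx(0, px0) + 1e-9, ph,
        "#000000",
        opacity = 0.06,
        data = c("data-role" = "motif-span", "data-ctx" = cx, "data-row" = rows[ri])
      ))
      if (rows[ri] == "methylation") {
        # translucent band at the background methylation probability
        mb <- profile$mbg$m[[cx]]
        add(prim_rect(px0, py0 + ph * (1 - mb) - 2, pw, 4, "#D95F02",
          opacity = 0.35,
          data = c(
            "data-role" = "bg-band", "data-ctx" = cx,
            "data-value" = fmt_data(mb)
          )
        ))
      }
      ok <- !is.na(vals)
      if (any(ok)) {
        add(prim_polyline(
          sx(offs[ok], px0),
          py0 + ph * (1 - pmin(vals[ok], ymax) / ymax),
          stroke = "#1F4E79",
          data = c(
            "data-role" = "scape-curve", "data-ctx" = cx,
            "data-row" = rows[ri], "data-n" = sum(ok)
          )
        ))
      }
      if (ci == 1L && cfg$show_axes) {
        lab <- c(
          entropy = "entropy (bits)", methylation = "methylation",
          context = "context prob."
        )[[rows[ri]]]
        add(prim_text(10, py0 + fs, lab, fs - 2, data = c("data-role" = "row-label")))
        add(prim_text(px0 - 4, py0 + fs - 2, fmt_axis(ymax), fs - 3, anchor = "end"))
        add(prim_text(px0 - 4, py0 + ph, "0", fs - 3, anchor = "end"))
      }
      if (ri == 3L && cfg$show_axes) {
        for (o in unique(c(xr[1L], 0, xr[2L]))) {
          add(prim_text(sx(o, px0), py0 + ph + fs + 2, as.character(o), fs - 3,
            anchor = "middle"
          ))
        }
      }
    }
  }
  scene(width, height, p)
}

# ---- SVG writer ------------------------------------------------------------

svg_num <- function(x) sprintf("%.6f", x)

svg_attrs <- function(v) {
  if (is.null(v) || length(v) == 0L) {
    return("")
  }
  paste0(" ", paste0(names(v), "=\"", v, "\"", collapse = " "))
}

scene_to_svg <- function(sc) {
  out <- character(0L)
  emit <- function(x) out[[length(out) + 1L]] <<- x
  emit("<?xml version=\"1.0\" encoding=\"UTF-8\"?>")
  emit(sprintf(
    "<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%s\" height=\"%s\" viewBox=\"0 0 %s %s\" font-family=\"sans-serif\">",
    svg_num(sc$width), svg_num(sc$height), svg_num(sc$width), svg_num(sc$height)
  ))
  emit(sprintf(
    "<rect x=\"0\" y=\"0\" width=\"%s\" height=\"%s\" fill=\"#FFFFFF\"/>",
    svg_num(sc$width), svg_num(sc$height)
  ))
  clip_id <- 0L
  for (pr in sc$prims) {
    da <- svg_attrs(pr$data)
    if (pr$kind == "rect") {
      op <- if (!is.na(pr$opacity)) sprintf(" fill-opacity=\"%s\"", svg_num(pr$opacity)) else ""
      st <- if (!is.na(pr$stroke)) sprintf(" stroke=\"%s\"", pr$stroke) else ""
      fill <- if (identical(pr$fill, "none")) "none" else pr$fill
      emit(sprintf(
        "<rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"%s\"%s%s%s/>",
        svg_num(pr$x), svg_num(pr$y), svg_num(pr$w), svg_num(pr$h), fill, st, op, da
      ))
    } else if (pr$kind == "line") {
      dsh <- if (!is.na(pr$dash)) sprintf(" stroke-dasharray=\"%s\"", pr$dash) else ""
      emit(sprintf(
        "<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"%s\" stroke-width=\"%s\"%s%s/>",
        svg_num(pr$x1), svg_num(pr$y1), svg_num(pr$x2), svg_num(pr$y2),
        pr$stroke, svg_num(pr$lwd), dsh, da
      ))
    } else if (pr$kind == "polyline") {
      pts <- paste(svg_num(pr$x), svg_num(pr$y), sep = ",", collapse = " ")
      emit(sprintf(
        "<polyline points=\"%s\" fill=\"none\" stroke=\"%s\" stroke-width=\"%s\"%s/>",
        pts, pr$stroke, svg_num(pr$lwd), da
      ))
    } else if (pr$kind == "text") {
      emit(sprintf(
        "<text x=\"%s\" y=\"%s\" font-size=\"%s\" text-anchor=\"%s\" fill=\"%s\"%s>%s</text>",
        svg_num(pr$x), svg_num(pr$y), svg_num(pr$size),
        c(start = "start", middle = "middle", end = "end")[[pr$anchor]],
        pr$fill, da, xml_escape(pr$str)
      ))
    } else if (pr$kind == "glyph") {
      d <- letter_path_d(pr$base)
      rule <- letter_paths[[pr$base]]$rule
      tr <- sprintf(
        "translate(%s,%s) scale(%s,%s)",
        svg_num(pr$x), svg_num(pr$y), svg_num(pr$w), svg_num(pr$h)
      )
      emit(sprintf("<g%s>", da))
      emit(sprintf(
        "<path d=\"%s\" fill=\"%s\" fill-rule=\"%s\" transform=\"%s\"/>",
        d, pr$fill, rule, tr
      ))
      if (!is.na(pr$shade) && pr$shade > 0) {
        clip_id <- clip_id + 1L
        cid <- sprintf("glyphclip%d", clip_id)
        emit(sprintf(
          "<clipPath id=\"%s\"><path d=\"%s\" clip-rule=\"%s\" transform=\"%s\"/></clipPath>",
          cid, d, rule, tr
        ))
        emit(sprintf(
          "<rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"%s\" clip-path=\"url(#%s)\" data-role=\"meth-shade\" data-frac=\"%s\"/>",
          svg_num(pr$x), svg_num(pr$y + (1 - pr$shade) * pr$h),
          svg_num(pr$w), svg_num(pr$shade * pr$h), pr$shade_fill, cid,
          fmt_data(pr$shade)
        ))
      }
      if (!is.na(pr$expected)) {
        emit(sprintf(
          "<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"#000000\" stroke-width=\"1.2\" stroke-dasharray=\"%s\" data-role=\"expected-line\" data-frac=\"%s\"/>",
          svg_num(pr$x - 2), svg_num(pr$y + (1 - pr$expected) * pr$h),
          svg_num(pr$x + pr$w + 2), svg_num(pr$y + (1 - pr$expected) * pr$h),
          pr$dash, fmt_data(pr$expected)
        ))
      }
      emit("</g>")
    }
  }
  emit("</svg>")
  paste0(paste(out, collapse = "\n"), "\n")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

write_scene_svg <- function(sc, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(scene_to_svg(sc)), con)
  invisible(path)
}

# ---- device backend (pdf/png and plot() on the active device) --------------

draw_scene_device <- function(sc) {
  op <- graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, sc$width), ylim = c(sc$height, 0))
  for (pr in sc$prims) {
    if (pr$kind == "rect") {
      fill <- if (identical(pr$fill, "none")) NA else pr$fill
      if (!is.na(pr$opacity) && !is.na(fill)) {
        fill <- grDevices::adjustcolor(fill, alpha.f = pr$opacity)
      }
      graphics::rect(pr$x, pr$y + pr$h, pr$x + pr$w, pr$y,
        col = fill,
        border = if (is.na(pr$stroke)) NA else pr$stroke
      )
    } else if (pr$kind == "line") {
      graphics::segments(pr$x1, pr$y1, pr$x2, pr$y2,
        col = pr$stroke,
        lty = if (is.na(pr$dash)) 1L else 2L, lwd = pr$lwd
      )
    } else if (pr$kind == "polyline") {
      graphics::lines(pr$x, pr$y, col = pr$stroke, lwd = pr$lwd)
    } else if (pr$kind == "text") {
      adj <- c(start = 0, middle = 0.5, end = 1)[[pr$anchor]]
      graphics::text(pr$x, pr$y, pr$str,
        adj = c(adj, 0), col = pr$fill,
        cex = pr$size / 12
      )
    } else if (pr$kind == "glyph") {
      lp <- letter_paths[[pr$base]]
      xs <- unlist(lapply(lp$subpaths, function(m) c(m[, 1L], NA)))
      ys <- unlist(lapply(lp$subpaths, function(m) c(m[, 2L], NA)))
      xs <- xs[-length(xs)]
      ys <- ys[-length(ys)]
      graphics::polypath(pr$x + xs * pr$w, pr$y + ys * pr$h,
        col = pr$fill,
        border = NA, rule = if (lp$rule == "evenodd") "evenodd" else "winding"
      )
      if (!is.na(pr$shade) && pr$shade > 0) {
        # base devices lack path clipping: overlay the lower fraction
        graphics::rect(pr$x, pr$y + pr$h, pr$x + pr$w,
          pr$y + (1 - pr$shade) * pr$h,
          col = grDevices::adjustcolor(pr$shade_fill, alpha.f = 0.45),
          border = NA
        )
      }
      if (!is.na(pr$expected)) {
        graphics::segments(pr$x - 2, pr$y + (1 - pr$expected) * pr$h,
          pr$x + pr$w + 2, pr$y + (1 - pr$expected) * pr$h,
          lty = 2L, lwd = 1.2
        )
      }
    }
  }
  invisible(NULL)
}

render_scene <- function(sc, out, cfg) {
  fmt <- cfg$format
  ext <- tolower(tools::file_ext(out))
  if (ext %in% c("svg", "pdf", "png")) fmt <- ext
  if (fmt == "svg") {
    write_scene_svg(sc, out)
  } else if (fmt == "pdf") {
    grDevices::pdf(out, width = sc$width / 72, height = sc$height / 72)
    on.exit(grDevices::dev.off())
    draw_scene_device(sc)
  } else {
    grDevices::png(out, width = sc$width, height = sc$height)
    on.exit(grDevices::dev.off())
    draw_scene_device(sc)
  }
  invisible(out)
}

#' Render a methylation-aware sequence logo
#'
#' Draws the three-track figure: methylation information on top (reverse-
#' strand components downward), the stacked-letter sequence logo in the
#' middle (C and G glyphs partially shaded to their observed methylation
#' level, with a dashed segment at the background-expected level), the dimer
#' information track at the bottom with its theoretical bounds, and a key box
#' listing the background methylation and base probabilities.
#'
#' SVG output is deterministic (byte-identical across runs for identical
#' inputs) and carries `data-*` attributes so every height and shading
#' fraction can be read back from the file.
#'
#' @param tracks A `track_set`.
#' @param motif The `motif_model` the tracks were computed from.
#' @param mbg A `bg_methyl` (for the key box).
#' @param bg0 A `bg_zero` (for the key box).
#' @param cfg A [render_config()].
#' @param out Output path; extension selects the format where recognised.
#' @return `out`, invisibly.
#' @export
render_logo <- function(tracks, motif, mbg, bg0, cfg = render_config(), out) {
  sc <- build_logo_scene(tracks, motif, mbg, bg0, cfg)
  render_scene(sc, out, cfg)
}

#' Render a flanking-window methylation profile panel
#'
#' A 3 x 3 grid: columns are the CpG, CHG and CHH contexts; rows show the
#' methylation relative entropy, the methylation probability (with a
#' translucent band at the background probability), and the context
#' probability, across the flanking window; the motif span is demarcated.
#'
#' @param profile A `scape_profile`.
#' @param cfg A [render_config()].
#' @param out Output path.
#' @return `out`, invisibly.
#' @export
render_methylscape <- function(profile, cfg = render_config(), out) {
  sc <- build_scape_scene(profile, cfg)
  render_scene(sc, out, cfg)
}
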
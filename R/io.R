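# Mesh writers (OFF / OBJ), catalog serialization (CSV / JSON) and the
# command-line interface.  All output is deterministic: stable orders and
# fixed 6-significant-digit float formatting.

fmt_num <- function(x) formatC(x, digits = 6, format = "g")

#' Write a mesh in OFF format
#'
#' Standard OFF layout: `OFF` header, a `V F E` counts line, vertex lines and
#' face lines prefixed by their arity (0-based indices).  Face labels are
#' appended as `#` comments.
#'
#' @param mesh a `capsid_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_off <- function(mesh, path) {
  stopifnot(inherits(mesh, "capsid_mesh"))
  V <- nrow(mesh$vertices); F <- length(mesh$faces)
  E <- sum(lengths(mesh$faces)) / 2
  lines <- c("OFF", sprintf("%d %d %d", V, F, E),
             apply(mesh$vertices, 1, function(v)
               paste(fmt_num(v), collapse = " ")),
             vapply(seq_along(mesh$faces), function(i)
               sprintf("%d %s  # %s", length(mesh$faces[[i]]),
                       paste(mesh$faces[[i]] - 1L, collapse = " "),
                       mesh$labels[i]),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read an OFF mesh
#'
#' Reads the subset of OFF written by [write_off()] (plus plain OFF files
#' without labels); trailing `#` comments are parsed back into face labels.
#'
#' @param path OFF file path.
#' @return A `capsid_mesh` (without design provenance).
#' @export
read_off <- function(path) {
  raw <- readLines(path)
  labels0 <- sub("^[^#]*#\\s*", "", raw)
  labels0[!grepl("#", raw)] <- NA_character_
  raw <- sub("#.*$", "", raw)
  raw <- trimws(raw)
  keepl <- nzchar(raw)
  toks <- raw[keepl]; labels0 <- labels0[keepl]
  if (toks[1] != "OFF") stop("not an OFF file: missing header")
  counts <- as.integer(strsplit(toks[2], "\\s+")[[1]])
  V <- counts[1]; F <- counts[2]
  verts <- do.call(rbind, lapply(toks[3:(2 + V)], function(l)
    as.numeric(strsplit(l, "\\s+")[[1]])))
  faces <- list(); labels <- character(F)
  for (i in seq_len(F)) {
    l <- strsplit(toks[2 + V + i], "\\s+")[[1]]
    n <- as.integer(l[1])
    faces[[i]] <- as.integer(l[2:(1 + n)]) + 1L
    labels[i] <- if (is.na(labels0[2 + V + i])) "face" else labels0[2 + V + i]
  }
  structure(list(vertices = verts, faces = faces, labels = labels,
                 design = NULL),
            class = "capsid_mesh")
}

#' Write a mesh in Wavefront OBJ format
#'
#' `v` records for vertices and `f` records with 1-based indices; face labels
#' are exported as `g` group records.
#'
#' @inheritParams write_off
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "capsid_mesh"))
  lines <- apply(mesh$vertices, 1, function(v)
    paste("v", paste(fmt_num(v), collapse = " ")))
  prev <- ""
  for (i in seq_along(mesh$faces)) {
    if (mesh$labels[i] != prev) {
      lines <- c(lines, paste("g", mesh$labels[i]))
      prev <- mesh$labels[i]
    }
    lines <- c(lines, paste("f", paste(mesh$faces[[i]], collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a design catalog
#'
#' @param rows a catalog data frame from [enumerate_designs()].
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(rows, path, format = c("csv", "json")) {
  format <- match.arg(format)
  rows <- as.data.frame(rows)
  num <- vapply(rows, function(x) is.numeric(x) && !all(x == round(x)),
                logical(1))
  for (nm in names(rows)[num]) rows[[nm]] <- as.numeric(fmt_num(rows[[nm]]))
  if (format == "csv") {
    utils::write.csv(rows, path, row.names = FALSE)
  } else {
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Parse a design string
#'
#' Syntax: `<lattice>[:dual]:h,k[@convention]` with lattice aliases `hex`,
#' `trihex`, `snub`, `rhombi` (or the full names).  Examples:
#' `"trihex:3,0"`, `"rhombi:dual:1,0"`, `"trihex:dual:1,0@rhomb_order_6"`.
#'
#' @param text design string.
#' @param symmetry symmetry class for the design.
#' @return A [capsid_design()].
#' @export
parse_design <- function(text, symmetry = "icosahedral") {
  parts <- strsplit(text, "@", fixed = TRUE)[[1]]
  convention <- if (length(parts) > 1L) parts[2] else NULL
  toks <- strsplit(parts[1], ":", fixed = TRUE)[[1]]
  if (length(toks) < 2L || length(toks) > 3L)
    stop(sprintf("cannot parse design '%s'; expected <lattice>[:dual]:h,k[@convention]",
                 text))
  lattice <- match_lattice_kind(toks[1])
  dual <- length(toks) == 3L
  if (dual && toks[2] != "dual")
    stop(sprintf("cannot parse design '%s': middle token must be 'dual'", text))
  hk <- suppressWarnings(as.integer(strsplit(toks[length(toks)], ",")[[1]]))
  if (length(hk) != 2L || anyNA(hk))
    stop(sprintf("cannot parse (h,k) from design '%s'", text))
  capsid_design(lattice, hk[1], hk[2], dual = dual, symmetry = symmetry,
                convention = convention)
}

cli_usage <- function() {
  paste(
    "usage: archicapsid <subcommand> [options]",
    "",
    "subcommands:",
    "  catalog  --max-T <real> [--symmetry icosahedral|octahedral|both]",
    "           [--kinds k1,k2,...] [--format csv|json|text] [--out FILE]",
    "  build    --lattice NAME --h H --k K [--dual] [--mirror] [--sphere]",
    "           [--symmetry ...] [--format off|obj] [--out FILE]",
    "  classify [--total N] [--mcp N] [--mmcp N] [--pentamers N] [--hexamers N]",
    "           [--trimers N] [--dimers N] [--tiles N] [--max-T T] [--portal]",
    "           [--format text|json] [--out FILE]",
    "  ratio    --ra R --rb R --design-a SPEC --design-b SPEC",
    "",
    "design strings: <lattice>[:dual]:h,k[@convention], lattice aliases",
    "hex, trihex, snub, rhombi; e.g. rhombi:dual:1,0 or trihex:3,0",
    sep = "\n")
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop(sprintf("unexpected argument '%s'", a))
    key <- substring(a, 3)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      flags[[key]] <- TRUE
      i <- i + 1L
    }
  }
  flags
}

flag_num <- function(flags, key, default = NA) {
  if (is.null(flags[[key]])) return(default)
  x <- suppressWarnings(as.numeric(flags[[key]]))
  if (is.na(x)) stop(sprintf("flag --%s needs a numeric value", key))
  x
}

#' Command-line interface
#'
#' Entry point for the `archicapsid` command (see `exec/archicapsid`).
#' Subcommands: `catalog` (write/print the design catalog), `build`
#' (construct a mesh and write OFF/OBJ), `classify` (match observed counts)
#' and `ratio` (radius-ratio test).  The tool is fully deterministic.
#'
#' @param args character vector of command-line arguments.
#' @return Exit status, invisibly: 0 on success, 2 on usage error.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L || args[1] %in% c("-h", "--help", "help")) {
      cat(cli_usage(), "\n")
      return(invisible(0L))
    }
    sub <- args[1]
    flags <- parse_flags(args[-1])
    sym <- flags[["symmetry"]]
    symmetry <- if (is.null(sym) || sym == "icosahedral") "icosahedral"
      else if (sym == "octahedral") "octahedral"
      else if (sym == "both") c("icosahedral", "octahedral")
      else stop("unknown symmetry: ", sym)
    switch(sub,
      catalog = {
        maxT <- flag_num(flags, "max-T")
        if (is.na(maxT)) stop("catalog requires --max-T")
        kinds <- if (is.null(flags[["kinds"]])) LATTICE_KINDS
          else strsplit(flags[["kinds"]], ",")[[1]]
        rows <- enumerate_designs(maxT, symmetry = symmetry, kinds = kinds)
        fmt <- if (is.null(flags[["format"]])) {
          if (is.null(flags[["out"]])) "text"
          else if (grepl("\\.json$", flags[["out"]])) "json" else "csv"
        } else flags[["format"]]
        if (is.null(flags[["out"]])) {
          if (fmt == "json")
            cat(jsonlite::toJSON(rows, auto_unbox = TRUE, digits = NA,
                                 pretty = TRUE), "\n")
          else
            print(rows[, c("T_label", "symmetry", "dual", "convention",
                           "n_MCP", "n_mCP", "n_total")], row.names = FALSE)
        } else {
          write_catalog(rows, flags[["out"]],
                        format = if (fmt == "text") "csv" else fmt)
          message("wrote ", nrow(rows), " catalog rows to ", flags[["out"]])
        }
      },
      build = {
        if (is.null(flags[["lattice"]])) stop("build requires --lattice")
        h <- flag_num(flags, "h"); k <- flag_num(flags, "k")
        if (is.na(h) || is.na(k)) stop("build requires --h and --k")
        d <- capsid_design(flags[["lattice"]], h, k,
                           dual = isTRUE(flags[["dual"]]),
                           symmetry = symmetry[1])
        m <- build_polyhedron(d, mirror = isTRUE(flags[["mirror"]]),
                              project_to_sphere = isTRUE(flags[["sphere"]]))
        out <- flags[["out"]]
        if (is.null(out)) stop("build requires --out")
        fmt <- if (is.null(flags[["format"]])) {
          if (grepl("\\.obj$", out)) "obj" else "off"
        } else flags[["format"]]
        if (fmt == "obj") write_obj(m, out) else write_off(m, out)
        cen <- mesh_census(m)
        message(sprintf("wrote %s mesh (V=%d, E=%d, F=%d) to %s",
                        t_label(d$lattice, d$hk[1], d$hk[2], d$dual),
                        cen$V, cen$E, cen$F, out))
      },
      classify = {
        obs <- capsid_observables(
          n_total = flag_num(flags, "total"),
          n_MCP = flag_num(flags, "mcp"),
          n_mCP = flag_num(flags, "mmcp"),
          pentamers = flag_num(flags, "pentamers"),
          hexamers = flag_num(flags, "hexamers"),
          trimers = flag_num(flags, "trimers"),
          dimers = flag_num(flags, "dimers"),
          tiles = flag_num(flags, "tiles"))
        hits <- classify_by_counts(obs,
                                   max_T = flag_num(flags, "max-T", 50),
                                   symmetry = symmetry,
                                   portal = isTRUE(flags[["portal"]]))
        if (identical(flags[["format"]], "json")) {
          txt <- jsonlite::toJSON(as.data.frame(hits), auto_unbox = TRUE,
                                  digits = NA, pretty = TRUE)
          if (is.null(flags[["out"]])) cat(txt, "\n")
          else writeLines(txt, flags[["out"]])
        } else {
          print(hits)
        }
      },
      ratio = {
        ra <- flag_num(flags, "ra"); rb <- flag_num(flags, "rb")
        if (is.na(ra) || is.na(rb)) stop("ratio requires --ra and --rb")
        if (is.null(flags[["design-a"]]) || is.null(flags[["design-b"]]))
          stop("ratio requires --design-a and --design-b")
        rt <- radius_ratio_test(ra, rb,
                                parse_design(flags[["design-a"]], symmetry[1]),
                                parse_design(flags[["design-b"]], symmetry[1]))
        print(rt)
      },
      stop(sprintf("unknown subcommand '%s'\n%s", sub, cli_usage())))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
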
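# Extended-XYZ reader/writer.  Dialect: frame = natoms line, then a
# comment line of Key=Value pairs (values optionally double-quoted) with
# Lattice="ax ay az bx by bz cx cy cz" (row-wise lattice vectors),
# Properties=name:type:ncols:... (types S/R/I/L) and optionally
# pbc="T T F", then natoms whitespace-separated atom lines.  Committee
# member forces are per-atom 3-columns named forces_0, forces_1, ...;
# reference forces are named forces_ref.  Units: eV, Angstrom.

parse_kv <- function(line) {
  pat <- '([A-Za-z_][A-Za-z0-9_]*)=("[^"]*"|\\S+)'
  m <- gregexpr(pat, line, perl = TRUE)[[1]]
  if (m[1] == -1) return(list())
  toks <- regmatches(line, gregexpr(pat, line, perl = TRUE))[[1]]
  keys <- sub("=.*$", "", toks)
  vals <- sub("^[^=]*=", "", toks)
  vals <- gsub('^"|"$', "", vals)
  setNames(as.list(vals), keys)
}

parse_properties <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) %% 3 != 0)
    stop_uq("malformed Properties entry: %s", spec)
  idx <- seq(1, length(parts), by = 3)
  data.frame(name = parts[idx], type = parts[idx + 1],
             ncols = as.integer(parts[idx + 2]))
}

#' Read a multi-frame extended-XYZ file
#'
#' Parses positions in Angstrom, the lattice (row-wise from the `Lattice`
#' entry), periodicity (from a `pbc` entry if present, otherwise inferred
#' from the presence of a lattice) and all declared per-atom columns.
#'
#' @param path file path.
#' @return a list of frames; each frame is a list with `config` (an
#'   [atomic_configuration()]), `arrays` (named per-atom columns beyond
#'   species/positions; 3-column properties become `(N_j, 3)` matrices)
#'   and `info` (remaining comment-line key/values).
#' @seealso [committee_from_frame()], [write_extxyz()]
#' @export
read_extxyz <- function(path) {
  if (!file.exists(path)) stop_uq("no such file: %s", path)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop_uq("line %d: expected an atom count, got '%s'", i, lines[i])
    if (i + 1L + n > length(lines))
      stop_uq("line %d: frame of %d atoms runs past end of file", i, n)
    info <- parse_kv(lines[i + 1L])
    props <- parse_properties(info$Properties %||% "species:S:1:pos:R:3")
    toks <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    want <- sum(props$ncols)
    bad <- which(lengths(toks) != want)
    if (length(bad))
      stop_uq("line %d: expected %d columns, got %d", i + 1L + bad[1],
              want, lengths(toks)[bad[1]])
    tab <- matrix(unlist(toks), nrow = n, byrow = TRUE)
    arrays <- list()
    col <- 1L
    for (p in seq_len(nrow(props))) {
      nc <- props$ncols[p]
      raw <- tab[, col:(col + nc - 1L), drop = FALSE]
      val <- switch(props$type[p],
                    S = raw,
                    R = matrix(as.numeric(raw), n, nc),
                    I = matrix(as.integer(raw), n, nc),
                    L = matrix(toupper(raw) %in% c("T", "TRUE"), n, nc),
                    stop_uq("line %d: unknown Properties type '%s'",
                            i + 1L, props$type[p]))
      if (nc == 1L && props$type[p] == "S") val <- as.character(val)
      arrays[[props$name[p]]] <- val
      col <- col + nc
    }
    if (is.null(arrays$species) || is.null(arrays$pos))
      stop_uq("line %d: Properties must include species and pos", i + 1L)
    cell <- NULL
    if (!is.null(info$Lattice)) {
      v <- as.numeric(strsplit(trimws(info$Lattice), "\\s+")[[1]])
      if (length(v) != 9L || any(!is.finite(v)))
        stop_uq("line %d: malformed Lattice entry", i + 1L)
      cell <- matrix(v, 3, 3, byrow = TRUE)
    }
    pbc <- if (!is.null(info$pbc)) {
      toupper(strsplit(trimws(info$pbc), "\\s+")[[1]]) %in% c("T", "TRUE")
    } else !is.null(cell)
    config <- atomic_configuration(arrays$species, arrays$pos, cell, pbc)
    extra <- arrays[setdiff(names(arrays), c("species", "pos"))]
    info <- info[setdiff(names(info), c("Lattice", "Properties", "pbc"))]
    frames[[length(frames) + 1L]] <-
      list(config = config, arrays = extra, info = info)
    i <- i + 2L + n
  }
  frames
}

fmt_num <- function(x) sprintf("%.16g", x)

#' Write frames as extended-XYZ
#'
#' Writes one or more frames (each an [atomic_configuration()], or a list
#' with `config`, optional named per-atom `arrays` and optional `info`
#' key/values) with full round-trip float precision.
#'
#' @param frames a single configuration/frame or a list of them.
#' @param path output file path.
#' @param comment optional provenance string added to every frame's
#'   comment line as `comment="..."`.
#' @return `path`, invisibly.
#' @export
write_extxyz <- function(frames, path, comment = NULL) {
  if (inherits(frames, "atomic_configuration")) frames <- list(frames)
  if (is.list(frames) && !is.null(frames$config)) frames <- list(frames)
  out <- character(0)
  for (fr in frames) {
    if (inherits(fr, "atomic_configuration")) fr <- list(config = fr)
    cfg <- fr$config
    arrays <- fr$arrays %||% list()
    n <- n_atoms(cfg)
    props <- "species:S:1:pos:R:3"
    cols <- cbind(cfg$species,
                  matrix(fmt_num(cfg$positions), n, 3))
    for (nm in names(arrays)) {
      a <- arrays[[nm]]
      if (is.null(dim(a))) a <- matrix(a, ncol = 1)
      check_same_shape(a[, 1], cfg$species, sprintf("array %s", nm))
      type <- if (is.numeric(a)) if (is.integer(a)) "I" else "R"
              else if (is.logical(a)) "L" else "S"
      props <- paste0(props, ":", nm, ":", type, ":", ncol(a))
      txt <- if (type == "R") matrix(fmt_num(a), nrow(a), ncol(a))
             else if (type == "L") ifelse(a, "T", "F")
             else a
      cols <- cbind(cols, txt)
    }
    kv <- character(0)
    if (!is.null(cfg$cell))
      kv <- c(kv, sprintf('Lattice="%s"',
                          paste(fmt_num(t(cfg$cell)), collapse = " ")))
    kv <- c(kv, sprintf("Properties=%s", props),
            sprintf('pbc="%s"', paste(ifelse(cfg$pbc, "T", "F"),
                                      collapse = " ")))
    for (nm in names(fr$info %||% list()))
      kv <- c(kv, sprintf('%s="%s"', nm, fr$info[[nm]]))
    if (!is.null(comment)) kv <- c(kv, sprintf('comment="%s"', comment))
    out <- c(out, as.character(n), paste(kv, collapse = " "),
             apply(cols, 1, paste, collapse = " "))
  }
  writeLines(out, path)
  invisible(path)
}

#' Collect committee forces from an extended-XYZ frame
#'
#' Gathers the suffix-indexed per-member force columns `forces_0`,
#' `forces_1`, ... of a frame read by [read_extxyz()] into a
#' [committee_forces()] object.
#'
#' @param frame one element of a [read_extxyz()] result.
#' @return a [committee_forces()] object.
#' @export
committee_from_frame <- function(frame) {
  nm <- grep("^forces_[0-9]+$", names(frame$arrays), value = TRUE)
  if (length(nm) < 2L)
    stop_uq("frame has %d member force columns; need at least 2", length(nm))
  nm <- nm[order(as.integer(sub("^forces_", "", nm)))]
  committee_forces(lapply(nm, function(k) frame$arrays[[k]]),
                   structure_id = frame$info$structure_id)
}

#' Reference forces of an extended-XYZ frame
#'
#' @param frame one element of a [read_extxyz()] result.
#' @return the `(N_j, 3)` `forces_ref` matrix, or `NULL` if absent.
#' @export
reference_from_frame <- function(frame) frame$arrays$forces_ref

#' Read/write (id, error, uncertainty) tables
#'
#' CSV plumbing for the calibration and sparsification tools.
#'
#' @param path CSV path with columns `id`, `error`, `uncertainty`.
#' @return `read_uq_table()`: a data.frame; `write_uq_table()`: `path`.
#' @export
read_uq_table <- function(path) {
  df <- read.csv(path)
  need <- c("error", "uncertainty")
  if (!all(need %in% names(df)))
    stop_uq("table must have columns error and uncertainty")
  df
}

#' @rdname read_uq_table
#' @param df data.frame with columns `id`, `error`, `uncertainty`.
#' @export
write_uq_table <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
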
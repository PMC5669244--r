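#' Run configuration for a metadynamics analysis
#'
#' Bundles the thermodynamic state, the collective-variable (CV) grid, the
#' bound/bulk CV windows used for adsorption free-energy extraction, and the
#' CV bin width used for the frame counts N(s) in the equal-weight
#' re-weighting scheme. Lengths are nm, energies kJ/mol, times ps.
#'
#' @param temperature simulation (ground-replica) temperature, K.
#' @param kB Boltzmann constant, kJ mol^-1 K^-1.
#' @param grid_min,grid_max,grid_n CV grid specification (nm, nm, points).
#' @param bound_region length-2 CV interval (nm) regarded as surface-bound.
#' @param bulk_region length-2 CV interval (nm) on the bulk plateau.
#' @param seed integer seed for any stochastic post-processing step.
#' @param binning CV bin width for N(s), nm.
#' @return an object of class `run_config`.
#' @export
#' @examples
#' cfg <- run_config(bound_region = c(0.3, 0.7), bulk_region = c(1.8, 2.2))
run_config <- function(temperature = 300, kB = KB_KJ_MOL_K,
                       grid_min = 0, grid_max = 4, grid_n = 801,
                       bound_region, bulk_region,
                       seed = 1L, binning = 0.02) {
  stopifnot(temperature > 0, kB > 0, grid_min < grid_max, grid_n >= 2,
            binning > 0)
  bound_region <- as.numeric(bound_region)
  bulk_region <- as.numeric(bulk_region)
  stopifnot(length(bound_region) == 2, length(bulk_region) == 2,
            bound_region[1] < bound_region[2], bulk_region[1] < bulk_region[2])
  if (bound_region[1] < grid_min || bound_region[2] > grid_max ||
      bulk_region[1] < grid_min || bulk_region[2] > grid_max)
    stop("bound and bulk regions must lie inside the CV grid")
  if (max(bound_region[1], bulk_region[1]) < min(bound_region[2], bulk_region[2]))
    stop("bound and bulk regions must be disjoint")
  structure(list(temperature = temperature, kB = kB,
                 grid_min = grid_min, grid_max = grid_max, grid_n = as.integer(grid_n),
                 bound_region = bound_region, bulk_region = bulk_region,
                 seed = as.integer(seed), binning = binning),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("run_config: T = %g K (kT = %.4f kJ/mol)\n", x$temperature,
              x$kB * x$temperature))
  cat(sprintf("  CV grid: [%g, %g] nm, %d points; N(s) bin %g nm\n",
              x$grid_min, x$grid_max, x$grid_n, x$binning))
  cat(sprintf("  bound region [%g, %g] nm; bulk region [%g, %g] nm; seed %d\n",
              x$bound_region[1], x$bound_region[2],
              x$bulk_region[1], x$bulk_region[2], x$seed))
  invisible(x)
}

#' CV grid from a run configuration
#' @param config a [run_config()].
#' @return numeric vector of CV grid values (nm).
#' @export
cv_grid <- function(config) {
  seq(config$grid_min, config$grid_max, length.out = config$grid_n)
}

#' Gaussian hill records
#'
#' One row per deposited metadynamics hill: time (ps), CV center (nm),
#' Gaussian width sigma (nm), height (kJ/mol) and, for well-tempered runs,
#' the bias factor. Heights are the heights actually deposited (i.e. already
#' scaled, for well-tempered deposition).
#'
#' @param time,center,sigma,height equal-length numeric vectors.
#' @param bias_factor optional numeric vector (recycled scalar allowed).
#' @return a data frame of class `hill_records`.
#' @export
hill_records <- function(time, center, sigma, height, bias_factor = NULL) {
  n <- length(time)
  if (length(sigma) == 1L) sigma <- rep(sigma, n)
  if (length(height) == 1L) height <- rep(height, n)
  stopifnot(length(center) == n, length(sigma) == n, length(height) == n)
  if (n > 0) {
    if (any(sigma <= 0)) stop("hill sigma must be > 0")
    if (any(height < 0)) stop("hill height must be >= 0")
    if (is.unsorted(time)) stop("hill times must be non-decreasing")
  }
  df <- data.frame(time = as.numeric(time), center = as.numeric(center),
                   sigma = as.numeric(sigma), height = as.numeric(height))
  if (!is.null(bias_factor)) df$bias_factor <- rep_len(as.numeric(bias_factor), n)
  class(df) <- c("hill_records", "data.frame")
  df
}

#' Time-aligned CV and observable series
#'
#' @param times frame times, ps (strictly increasing).
#' @param cv CV values s(t), nm.
#' @param observables named list of per-frame numeric vectors.
#' @return an object of class `frame_series`.
#' @export
frame_series <- function(times, cv, observables = list()) {
  n <- length(times)
  stopifnot(length(cv) == n)
  if (n > 1 && any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  if (length(observables)) {
    if (is.null(names(observables)) || any(names(observables) == ""))
      stop("observables must be a named list")
    bad <- names(observables)[vapply(observables, length, 1L) != n]
    if (length(bad)) stop("observable length mismatch: ", paste(bad, collapse = ", "))
  }
  structure(list(times = as.numeric(times), cv = as.numeric(cv),
                 observables = observables),
            class = "frame_series")
}

#' @export
length.frame_series <- function(x) length(x$times)

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("frame_series: %d frames, t = [%g, %g] ps, cv in [%.3f, %.3f] nm\n",
              length(x), if (length(x)) min(x$times) else NA,
              if (length(x)) max(x$times) else NA,
              if (length(x)) min(x$cv) else NA,
              if (length(x)) max(x$cv) else NA))
  if (length(x$observables))
    cat("  observables:", paste(names(x$observables), collapse = ", "), "\n")
  invisible(x)
}

#' Restrict a frame series to a time or CV window
#'
#' @param frames a [frame_series()].
#' @param t_min,t_max keep frames with t_min <= t <= t_max.
#' @param cv_range optional length-2 CV interval; keep frames inside it
#'   (closed interval).
#' @return a `frame_series` with the retained frames.
#' @export
subset_frames <- function(frames, t_min = -Inf, t_max = Inf, cv_range = NULL) {
  keep <- frames$times >= t_min & frames$times <= t_max
  if (!is.null(cv_range))
    keep <- keep & frames$cv >= cv_range[1] & frames$cv <= cv_range[2]
  frame_series(frames$times[keep], frames$cv[keep],
               lapply(frames$observables, function(v) v[keep]))
}

# ---- column files (enhanced-sampling dialect: "#! FIELDS ..." header) -------

read_column_file <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  hdr_i <- grep("^#!", lines)[1]
  if (is.na(hdr_i)) stop("no '#! FIELDS' header line in ", path)
  hdr <- strsplit(sub("^#!\\s*", "", lines[hdr_i]), "\\s+")[[1]]
  if (toupper(hdr[1]) != "FIELDS") stop("header must start with '#! FIELDS' in ", path)
  fields <- hdr[-1]
  data_lines <- lines[-seq_len(hdr_i)]
  # tolerate trailing comments and blank lines
  data_lines <- sub("#.*$", "", data_lines)
  keep <- grepl("\\S", data_lines)
  data_lines <- trimws(data_lines[keep])
  line_no <- (seq_along(lines))[-seq_len(hdr_i)][keep]
  if (!length(data_lines))
    return(list(fields = fields,
                data = matrix(numeric(0), 0, length(fields),
                              dimnames = list(NULL, fields))))
  toks <- strsplit(data_lines, "\\s+")
  nf <- lengths(toks)
  bad <- which(nf != length(fields))
  if (length(bad))
    stop(sprintf("parse error in %s at line %d: expected %d fields, found %d",
                 path, line_no[bad[1]], length(fields), nf[bad[1]]))
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  nas <- which(is.na(vals))
  if (length(nas))
    stop(sprintf("parse error in %s at line %d: non-numeric value",
                 path, line_no[ceiling(nas[1] / length(fields))]))
  m <- matrix(vals, ncol = length(fields), byrow = TRUE,
              dimnames = list(NULL, fields))
  list(fields = fields, data = m)
}

write_column_file <- function(m, fields, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(fields, collapse = " ")), con)
  if (nrow(m))
    writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
               con)
  invisible(path)
}

#' Read a metadynamics hills file
#'
#' Expects a single header line `#! FIELDS time <cv> sigma height [biasf]`
#' followed by whitespace-delimited rows; repeated whitespace and trailing
#' `#` comments are tolerated.
#'
#' @param path file path.
#' @return a [hill_records()] data frame, one record per data row.
#' @export
read_hills <- function(path) {
  cf <- read_column_file(path)
  f <- cf$fields
  if (length(f) < 4) stop("hills file needs at least time, <cv>, sigma, height columns")
  need <- c("time", "sigma", "height")
  if (!all(need %in% f)) stop("hills file must name columns: ",
                              paste(setdiff(need, f), collapse = ", "))
  cv_col <- setdiff(f, c("time", "sigma", "height", "biasf"))[1]
  m <- cf$data
  hill_records(m[, "time"], m[, cv_col], m[, "sigma"], m[, "height"],
               bias_factor = if ("biasf" %in% f) m[, "biasf"] else NULL)
}

#' Write a metadynamics hills file
#'
#' @param hills a [hill_records()] data frame.
#' @param path file path.
#' @param cv_name name used for the CV column.
#' @return `path`, invisibly.
#' @export
write_hills <- function(hills, path, cv_name = "s") {
  fields <- c("time", cv_name, "sigma", "height")
  m <- cbind(hills$time, hills$center, hills$sigma, hills$height)
  if (!is.null(hills$bias_factor)) {
    fields <- c(fields, "biasf")
    m <- cbind(m, hills$bias_factor)
  }
  if (!length(hills$time)) m <- matrix(numeric(0), 0, length(fields))
  write_column_file(m, fields, path)
}

#' Read a CV/observable time-series file
#'
#' @param path file path with header `#! FIELDS time <cv> [observables...]`.
#' @param observable_names observable columns to load (must be present).
#' @param cv_name name of the CV column; by default the first non-time column.
#' @return a [frame_series()].
#' @export
read_frames <- function(path, observable_names = character(), cv_name = NULL) {
  cf <- read_column_file(path)
  f <- cf$fields
  if (!"time" %in% f) stop("frames file must name a 'time' column")
  if (is.null(cv_name)) cv_name <- setdiff(f, "time")[1]
  if (is.na(cv_name) || !cv_name %in% f) stop("frames file has no CV column")
  missing_obs <- setdiff(observable_names, f)
  if (length(missing_obs))
    stop("missing observable column(s): ", paste(missing_obs, collapse = ", "))
  m <- cf$data
  obs <- lapply(observable_names, function(o) m[, o])
  names(obs) <- observable_names
  frame_series(m[, "time"], m[, cv_name], obs)
}

#' Write a CV/observable time-series file
#'
#' @param frames a [frame_series()].
#' @param path file path.
#' @param cv_name name used for the CV column.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path, cv_name = "s") {
  fields <- c("time", cv_name, names(frames$observables))
  m <- cbind(frames$times, frames$cv)
  for (o in frames$observables) m <- cbind(m, o)
  if (!length(frames$times)) m <- matrix(numeric(0), 0, length(fields))
  write_column_file(m, fields, path)
}

# ---- slab snapshot frames (minimal GRO dialect) -----------------------------

#' A single slab snapshot
#'
#' Carrier for the structural analyses: orthorhombic box, the mean height of
#' the top gold layer, per-residue side-chain reference-atom positions, and
#' water oxygen positions. All coordinates in nm.
#'
#' @param box length-3 box edge lengths (nm).
#' @param gold_top_z mean z of the top gold layer (nm).
#' @param residue_refs named list; each element an n x 3 matrix of reference
#'   atom positions for one residue.
#' @param water_oxygens m x 3 matrix of water oxygen positions.
#' @param weight_hint optional frame weight.
#' @return an object of class `slab_frame`.
#' @export
slab_frame <- function(box, gold_top_z, residue_refs, water_oxygens,
                       weight_hint = NULL) {
  box <- as.numeric(box)
  stopifnot(length(box) == 3, all(box > 0))
  if (gold_top_z < 0 || gold_top_z > box[3])
    stop("gold_top_z must lie within the box z-range")
  water_oxygens <- as_coord_matrix(water_oxygens)
  residue_refs <- lapply(residue_refs, as_coord_matrix)
  all_xyz <- rbind(water_oxygens, do.call(rbind, residue_refs))
  if (nrow(all_xyz)) {
    tol <- 1e-6
    inside <- all_xyz[, 1] >= -tol & all_xyz[, 1] <= box[1] + tol &
      all_xyz[, 2] >= -tol & all_xyz[, 2] <= box[2] + tol &
      all_xyz[, 3] >= -tol & all_xyz[, 3] <= box[3] + tol
    if (!all(inside)) stop("coordinates outside the box")
  }
  structure(list(box = box, gold_top_z = gold_top_z,
                 residue_refs = residue_refs, water_oxygens = water_oxygens,
                 weight_hint = weight_hint),
            class = "slab_frame")
}

as_coord_matrix <- function(x) {
  m <- as.matrix(x)
  if (!ncol(m) == 3) stop("coordinates must be an n x 3 matrix")
  storage.mode(m) <- "double"
  m
}

#' @export
print.slab_frame <- function(x, ...) {
  cat(sprintf("slab_frame: box %g x %g x %g nm, gold top at z = %.3f nm\n",
              x$box[1], x$box[2], x$box[3], x$gold_top_z))
  cat(sprintf("  %d residues, %d water oxygens\n",
              length(x$residue_refs), nrow(x$water_oxygens)))
  invisible(x)
}

fmt_gro_atom <- function(resid, resname, atom, atomno, xyz) {
  sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", resid %% 100000, resname, atom,
          atomno %% 100000, xyz[1], xyz[2], xyz[3])
}

#' Write slab snapshots as concatenated GRO frames
#'
#' Gold atoms are written as residue `AU`/atom `AU`, waters as `SOL`/`OW`,
#' residue reference atoms under their residue key (e.g. `TRP1` becomes
#' residue name `TRP`, residue number 1).
#'
#' @param frames list of [slab_frame()] objects.
#' @param path file path.
#' @param gold_xy optional k x 2 matrix of in-plane gold positions; a small
#'   default grid is used when omitted (two layers 0.235 nm apart).
#' @return `path`, invisibly.
#' @export
write_slab_frames <- function(frames, path, gold_xy = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    if (is.null(gold_xy)) {
      gx <- seq(0.125, fr$box[1] - 0.1, by = 0.25)
      gy <- seq(0.125, fr$box[2] - 0.1, by = 0.25)
      gold_xy <- as.matrix(expand.grid(gx, gy))
    }
    lines <- character(0)
    atomno <- 0L
    resid <- 0L
    for (layer_dz in c(0, -0.235)) {
      z <- fr$gold_top_z + layer_dz
      if (z < 0) next
      for (k in seq_len(nrow(gold_xy))) {
        atomno <- atomno + 1L
        resid <- resid + 1L
        lines <- c(lines, fmt_gro_atom(resid, "AU", "AU", atomno,
                                       c(gold_xy[k, 1], gold_xy[k, 2], z)))
      }
    }
    for (key in names(fr$residue_refs)) {
      resname <- gsub("[0-9]+$", "", key)
      rid <- as.integer(gsub("^[A-Za-z]+", "", key))
      m <- fr$residue_refs[[key]]
      anames <- rownames(m)
      if (is.null(anames)) anames <- paste0("R", seq_len(nrow(m)))
      for (k in seq_len(nrow(m))) {
        atomno <- atomno + 1L
        lines <- c(lines, fmt_gro_atom(rid, resname, anames[k], atomno, m[k, ]))
      }
    }
    nw <- nrow(fr$water_oxygens)
    if (nw) {
      for (k in seq_len(nw)) {
        atomno <- atomno + 1L
        resid <- resid + 1L
        lines <- c(lines, fmt_gro_atom(resid, "SOL", "OW", atomno,
                                       fr$water_oxygens[k, ]))
      }
    }
    writeLines("toygold slab frame", con)
    writeLines(sprintf("%5d", length(lines)), con)
    writeLines(lines, con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3]), con)
  }
  invisible(path)
}

#' Read slab snapshots from concatenated GRO frames
#'
#' @param path file path.
#' @param residue_atom_map named list mapping residue keys (`<RESNAME><resid>`,
#'   e.g. `"TRP1"`) to character vectors of reference atom names.
#' @return list of [slab_frame()] objects.
#' @export
read_slab_frames <- function(path, residue_atom_map) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("\\S", lines[i])) { i <- i + 1L; next }
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms)) stop("malformed GRO frame near line ", i + 1L)
    atom_lines <- lines[(i + 2L):(i + 1L + natoms)]
    box_line <- lines[i + 2L + natoms]
    box <- as.numeric(strsplit(trimws(box_line), "\\s+")[[1]])[1:3]
    resid <- as.integer(substr(atom_lines, 1, 5))
    resname <- trimws(substr(atom_lines, 6, 10))
    atom <- trimws(substr(atom_lines, 11, 15))
    x <- as.numeric(substr(atom_lines, 21, 28))
    y <- as.numeric(substr(atom_lines, 29, 36))
    z <- as.numeric(substr(atom_lines, 37, 44))
    if (anyNA(c(x, y, z))) stop("malformed coordinates in GRO frame near line ", i)

    gold <- resname == "AU"
    if (!any(gold)) stop("no gold atoms (residue AU) in frame near line ", i)
    gz <- z[gold]
    gold_top_z <- mean(gz[gz >= max(gz) - 0.08])

    key_all <- paste0(resname, resid)
    refs <- lapply(names(residue_atom_map), function(key) {
      want <- residue_atom_map[[key]]
      sel <- key_all == key & atom %in% want
      found <- atom[sel]
      missing <- setdiff(want, found)
      if (length(missing))
        stop(sprintf("atom(s) %s of residue %s absent from frame",
                     paste(missing, collapse = ","), key))
      m <- cbind(x[sel], y[sel], z[sel])
      rownames(m) <- found
      m
    })
    names(refs) <- names(residue_atom_map)

    wat <- resname == "SOL" & atom == "OW"
    frames[[length(frames) + 1L]] <-
      slab_frame(box, gold_top_z, refs, cbind(x[wat], y[wat], z[wat]))
    i <- i + 3L + natoms
  }
  frames
}

# ---- flat key = value configuration files -----------------------------------

#' Read a flat `key = value` configuration file
#'
#' Values are parsed as numeric vectors when possible (comma-separated),
#' otherwise kept as strings. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[grepl("\\S", lines) & !grepl("^\\s*#", lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln)) stop("configuration line without '=': ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}

#' Write a flat `key = value` configuration file
#'
#' @param config named list of scalars / numeric vectors / strings.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste(k, "=", paste(formatC(unlist(v), digits = 12, format = "g"),
                        collapse = ", "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
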
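#' NIfTI volume I/O
#'
#' Images are read from NIfTI-1 files and min-max normalized to [0, 1] (the
#' solver's intensity convention); label maps are read as integers without
#' rescaling. The solver always works on the normalized periodic domain
#' \eqn{[0,2\pi)^3}; physical voxel spacing from the header is recorded but
#' not modeled.
#'
#' @param path path to a 3D NIfTI-1 file.
#' @param type \code{"image"} (normalized) or \code{"labels"}
#'   (integer-valued, checked).
#' @return a 3D array with attributes \code{pixdim} (recorded voxel spacing)
#'   and, for constant images, \code{degenerate}.
#' @export
read_volume <- function(path, type = c("image", "labels")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D volume")
  if (anyNA(arr) || !all(is.finite(arr))) stop("volume contains NaN/Inf values")
  pixdim <- RNifti::pixdim(img)
  if (type == "labels") {
    if (any(arr != round(arr))) stop("label volume contains non-integer values")
    out <- array(as.integer(arr), dim = dim(arr))
    attr(out, "pixdim") <- pixdim
    return(out)
  }
  lo <- min(arr); hi <- max(arr)
  if (hi == lo) {
    warning("degenerate intensity range; image normalized to all zeros")
    out <- array(0, dim = dim(arr))
    attr(out, "degenerate") <- TRUE
  } else {
    out <- (arr - lo) / (hi - lo)
  }
  attr(out, "pixdim") <- pixdim
  out
}

#' Write a 3D array as NIfTI
#'
#' Images are stored as float64 (value-exact round trip), label maps as int32.
#'
#' @param x 3D array (or 4D velocity; written componentwise by
#'   \code{write_velocity}).
#' @param path output path (.nii or .nii.gz).
#' @param datatype passed to RNifti (\code{"double"} or \code{"int32"}).
#' @export
write_volume <- function(x, path, datatype = "double") {
  arr <- array(if (datatype == "int32") as.integer(x) else as.numeric(x),
               dim = dim(x)[1:3])
  RNifti::writeNifti(RNifti::asNifti(arr), path, datatype = datatype)
  invisible(path)
}

write_velocity <- function(v, dir, prefix = "velocity") {
  paths <- file.path(dir, sprintf("%s_x%d.nii.gz", prefix, 1:3))
  for (a in 1:3) write_volume(v[, , , a], paths[a])
  invisible(paths)
}

read_velocity <- function(dir, grid, prefix = "velocity") {
  v <- vector_field(grid)
  for (a in 1:3) {
    arr <- as.array(RNifti::readNifti(file.path(dir, sprintf("%s_x%d.nii.gz", prefix, a))))
    v[, , , a] <- arr
  }
  v
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}

# ---- command-line interface -------------------------------------------------

cli_usage <- function() {
  paste(
    "usage: velreg.R <command> [options]",
    "",
    "commands:",
    "  register  --template T.nii --reference R.nii --beta-v B [--beta-w B] ...",
    "  search    --template T.nii --reference R.nii [--jmin J] ...",
    "  continue  --template T.nii --reference R.nii --beta-v B --beta-w B ...",
    "  synth     --out DIR [--n N] [--K K] [--seed S]",
    "  multires  --template T.nii --reference R.nii --labels0 L0.nii --labels1 L1.nii ...",
    "  metrics   --labels0 L0.nii --labels1 L1.nii",
    "",
    "common options: --out DIR, --nt N, --interp linear|cubic, --gtol G,",
    "                --jmin J, --seed S, --maxit N",
    sep = "\n"
  )
}

cli_opts <- function(args) {
  # minimal --key value parser (all values scalar strings)
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop(sprintf("unexpected argument: %s", a))
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}

cli_cfg <- function(o) {
  solver_config(
    gtol = as.numeric(o[["gtol"]] %||% 5e-2),
    maxit = as.integer(o[["maxit"]] %||% 50L),
    scheme = o[["interp"]] %||% "cubic",
    nt = as.integer(o[["nt"]] %||% 4L),
    verbose = isTRUE(o[["verbose"]])
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cli_write_fit <- function(fit, grid, outdir, m1, extra = list()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_velocity(fit$v, outdir)
  write_volume(fit$m_final, file.path(outdir, "deformed_template.nii.gz"))
  write_volume(fit$jac, file.path(outdir, "jacobian_det.nii.gz"))
  write_volume(abs(fit$m_final - m1), file.path(outdir, "residual.nii.gz"))
  diag <- c(list(
    converged = fit$converged, iterations = fit$iterations,
    r = fit$r, jac_min = fit$jac_range[1], jac_max = fit$jac_range[2],
    beta_v = fit$params$beta_v, beta_w = fit$params$beta_w,
    objective = fit$objective, gradnorm = fit$gradnorm,
    nt = fit$config$nt, scheme = fit$config$scheme, gtol = fit$config$gtol,
    package_version = as.character(utils::packageVersion("velreg"))
  ), extra)
  write_json_report(diag, file.path(outdir, "diagnostics.json"))
}

#' Command-line entry point
#'
#' Thin dispatcher behind \code{inst/cli/velreg.R}; see \code{cli_usage()}
#' output for the subcommands. Returns the process exit code: 0 on success
#' (converged where applicable), 2 for a non-converged registration, 1 on
#' usage or data errors.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code, invisibly.
#' @export
run_cli <- function(args) {
  code <- tryCatch({
    if (length(args) < 1L) {
      message(cli_usage())
      return(invisible(1L))
    }
    cmd <- args[1]
    o <- cli_opts(args[-1])
    if (!is.null(o[["seed"]])) set.seed(as.integer(o[["seed"]]))
    switch(cmd,
      synth = {
        outdir <- o[["out"]] %||% stop("synth requires --out")
        n <- as.integer(o[["n"]] %||% 64L)
        grid <- make_grid(rep(n, 3))
        pair <- make_pair(grid, K = as.integer(o[["K"]] %||% 4L),
                          seed = as.integer(o[["seed"]] %||% 1L))
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
        write_volume(pair$m0, file.path(outdir, "template.nii.gz"))
        write_volume(pair$m1, file.path(outdir, "reference.nii.gz"))
        write_volume(pair$labels0, file.path(outdir, "labels0.nii.gz"), "int32")
        write_volume(pair$labels1, file.path(outdir, "labels1.nii.gz"), "int32")
        write_velocity(pair$v_true, outdir, "velocity_true")
        write_json_report(list(seed = pair$seed, K = as.integer(o[["K"]] %||% 4L),
                               n = n, label_values = pair$label_values,
                               offsets = pair$spec$offsets,
                               theta_shift = pair$spec$theta_shift,
                               phi_shift = pair$spec$phi_shift),
                          file.path(outdir, "synth_spec.json"))
        0L
      },
      metrics = {
        l0 <- read_volume(o[["labels0"]] %||% stop("metrics requires --labels0"), "labels")
        l1 <- read_volume(o[["labels1"]] %||% stop("metrics requires --labels1"), "labels")
        rep <- dice_report(l0, l1)
        out <- list(Da = rep$Da, Dvw = rep$Dvw, Divw = rep$Divw,
                    per_label = rep$per_label)
        if (!is.null(o[["out"]])) {
          dir.create(o[["out"]], recursive = TRUE, showWarnings = FALSE)
          write_json_report(out, file.path(o[["out"]], "dice.json"))
        }
        print(rep)
        0L
      },
      register = ,
      search = ,
      `continue` = {
        m0 <- read_volume(o[["template"]] %||% stop(sprintf("%s requires --template", cmd)))
        m1 <- read_volume(o[["reference"]] %||% stop(sprintf("%s requires --reference", cmd)))
        if (!identical(dim(m0), dim(m1))) stop("template and reference dimensions differ")
        grid <- make_grid(dim(m0))
        cfg <- cli_cfg(o)
        outdir <- o[["out"]] %||% "."
        if (cmd == "register") {
          p <- reg_params(as.numeric(o[["beta-v"]] %||% stop("register requires --beta-v")),
                          as.numeric(o[["beta-w"]] %||% 0))
          fit <- gauss_newton(m0, m1, grid, p, cfg)
          cli_write_fit(fit, grid, outdir, m1, list(mode = "fixed"))
          if (fit$converged) 0L else 2L
        } else if (cmd == "search") {
          bounds <- jac_bounds(as.numeric(o[["jmin"]] %||% 0.25))
          sr <- parameter_search(m0, m1, grid, bounds, cfg)
          dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
          utils::write.csv(sr$trace, file.path(outdir, "search_trace.csv"),
                           row.names = FALSE)
          if (!sr$success) stop("parameter search failed")
          cli_write_fit(sr$fit, grid, outdir, m1,
                        list(mode = "search", jmin = bounds$jmin))
          if (sr$fit$converged) 0L else 2L
        } else {
          p <- reg_params(as.numeric(o[["beta-v"]] %||% stop("continue requires --beta-v")),
                          as.numeric(o[["beta-w"]] %||% BETA_W_MIN))
          fit <- parameter_continuation(m0, m1, grid, p, cfg)
          dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
          utils::write.csv(fit$ladder, file.path(outdir, "continuation_ladder.csv"),
                           row.names = FALSE)
          cli_write_fit(fit, grid, outdir, m1, list(mode = "continuation"))
          if (fit$converged) 0L else 2L
        }
      },
      multires = {
        m0 <- read_volume(o[["template"]] %||% stop("multires requires --template"))
        m1 <- read_volume(o[["reference"]] %||% stop("multires requires --reference"))
        l0 <- read_volume(o[["labels0"]] %||% stop("multires requires --labels0"), "labels")
        l1 <- read_volume(o[["labels1"]] %||% stop("multires requires --labels1"), "labels")
        grid <- make_grid(dim(m0))
        cfg <- cli_cfg(o)
        levels <- as.integer(strsplit(o[["levels"]] %||% "1,2,4", ",")[[1]])
        rep <- multires_experiment(m0, m1, l0, l1, grid, levels,
                                   jac_bounds(as.numeric(o[["jmin"]] %||% 0.05)), cfg)
        outdir <- o[["out"]] %||% "."
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(rep, file.path(outdir, "multires_report.csv"),
                         row.names = FALSE)
        print(rep)
        0L
      },
      {
        message(cli_usage())
        1L
      }
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    message(cli_usage())
    1L
  })
  invisible(as.integer(code))
}
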
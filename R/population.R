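# Genome census, protocell taxonomy, population protocol and statistics.

#' Vesicle classes
#'
#' The taxonomy of protocells that RNA segregation at division can produce:
#' \describe{
#'   \item{EMPTY}{no RNA strands at all; grows only by lipid exchange.}
#'   \item{INERT}{strands present but no catalytic capability (a lone R_P,
#'     or only complementary strands).}
#'   \item{SELF_PRODUCING}{has R_L but no polymerase: synthesises lipid,
#'     grows and divides, but cannot replicate its genome.}
#'   \item{SELF_REPLICATING_GENOME}{can replicate its (polymerase-only)
#'     genome but not the membrane; destined for osmotic burst from waste
#'     accumulation.}
#'   \item{REDUCED_RIBOCELL}{one R_P plus lipase-gene strands: replicates
#'     the lipase gene and synthesises lipid, but cannot replicate R_P.}
#'   \item{RIBOCELL}{full minimal kit (at least one catalytic R_P, a
#'     polymerase-gene template and a lipase-gene strand): self-replicates
#'     genome and membrane.}
#'   \item{BROKEN}{burst; persists in the census as a flat bilayer.}
#' }
#' @export
vesicle_classes <- c("EMPTY", "INERT", "SELF_PRODUCING",
                     "SELF_REPLICATING_GENOME", "REDUCED_RIBOCELL",
                     "RIBOCELL", "BROKEN")

#' Genome census of a vesicle
#'
#' Total strand counts of R_P, cR_P, R_L and cR_L — decomposing dimers and
#' elongation complexes into their constituent strands (a complex counts its
#' polymerase and template; the nascent chain counts only once complete) —
#' plus the free-monomer counts, which are what carries catalytic activity.
#'
#' @param state [vesicle_state()] (or a bare named counts vector).
#' @param registry [build_species_registry()].
#' @return Object of class \code{genome_tally}: list with \code{totals} and
#'   \code{free}, each a named vector over the four strand types.
#' @export
tally_genome <- function(state, registry) {
  counts <- if (inherits(state, "vesicle_state")) state$counts else state
  totals <- as.vector(counts %*% registry$strands)
  names(totals) <- colnames(registry$strands)
  free <- counts[registry$idx$monomers]
  names(free) <- names(registry$idx$monomers)
  structure(list(totals = totals, free = free), class = "genome_tally")
}

#' Classify a vesicle by status and genome census
#'
#' Total function of (status, tally) implementing the capability-based
#' precedence rules: BROKEN; EMPTY (no strands); RIBOCELL (R_P >= 1 and a
#' polymerase-gene template, i.e. R_P >= 2 or cR_P >= 1, and at least one
#' lipase-gene strand); REDUCED_RIBOCELL (exactly one R_P, no cR_P, lipase
#' strands present); SELF_REPLICATING_GENOME (replicable polymerase gene,
#' no lipase strands); SELF_PRODUCING (R_L present, no polymerase); else
#' INERT (e.g. a lone R_P, or only complementary strands).
#'
#' @param status \code{"intact"} or \code{"broken"}.
#' @param tally a [tally_genome()] result (or a named totals vector).
#' @return One of [vesicle_classes].
#' @export
classify_vesicle <- function(status, tally) {
  if (identical(status, "broken")) return("BROKEN")
  tot <- if (inherits(tally, "genome_tally")) tally$totals else tally
  RP <- tot[["R_P"]]; cRP <- tot[["cR_P"]]
  Lst <- tot[["R_L"]] + tot[["cR_L"]]
  if (sum(tot) == 0) return("EMPTY")
  if (RP >= 1 && (RP >= 2 || cRP >= 1) && Lst >= 1) return("RIBOCELL")
  if (RP == 1 && cRP == 0 && Lst >= 1) return("REDUCED_RIBOCELL")
  if ((RP >= 2 || (RP >= 1 && cRP >= 1)) && Lst == 0)
    return("SELF_REPLICATING_GENOME")
  if (tot[["R_L"]] >= 1 && RP == 0) return("SELF_PRODUCING")
  "INERT"
}

#' Run a stochastic population with the keep-one-daughter protocol
#'
#' Simulates \code{n_runs} statistically equivalent runs of
#' \code{vesicles_per_run} vesicles each. At every division only one
#' daughter is kept (per \code{opts$keep_daughter_policy}) so the number of
#' monitored entities stays constant; broken vesicles remain counted. Each
#' vesicle is followed until \code{opts$max_generations} divisions or
#' \code{opts$max_sim_time_days}; the class census is recorded on a regular
#' time grid.
#'
#' @param network,env,geom,consts model specification.
#' @param ic founder [vesicle_state()] (each entity starts from an
#'   integer-rounded copy).
#' @param n_runs number of replicate runs (each gets its own seed derived
#'   from the master seed).
#' @param vesicles_per_run entities per run.
#' @param opts [ssa_options()]; \code{opts$seed} is the master seed.
#' @param snapshot_every_days census recording interval.
#' @return Object of class \code{population_record}: \code{divisions}
#'   (run, vesicle, generation, t_div_days, delta_t_days, class_after),
#'   \code{snapshots} (run, vesicle, time_days, class), \code{n_entities},
#'   \code{seeds}.
#' @export
run_population <- function(network, ic, env = environment_spec(),
                           geom = geometry_params(),
                           consts = physical_constants(),
                           n_runs = 4, vesicles_per_run = 10,
                           opts = ssa_options(), snapshot_every_days = 10) {
  if (!is.null(opts$seed)) set.seed(opts$seed)
  seeds <- sample.int(.Machine$integer.max - 1, n_runs)
  xptr <- .compile_network(network, env, geom, consts)
  reg <- network$registry
  t_end <- opts$max_sim_time_days * .DAY
  snaps_t <- seq(0, opts$max_sim_time_days, by = snapshot_every_days)

  div_rows <- list(); snap_rows <- list()
  for (r in seq_len(n_runs)) {
    set.seed(seeds[r])
    for (v in seq_len(vesicles_per_run)) {
      st <- ic
      st$counts <- round(ic$counts)
      st$lineage_id <- sprintf("r%d.v%d", r, v)
      t <- 0; gen <- 0L; t_last_div <- 0
      classes <- character(length(snaps_t)); ci <- 1
      note <- function(upto) { # record census up to time 'upto' (s)
        while (ci <= length(snaps_t) && snaps_t[ci] * .DAY <= upto) {
          classes[ci] <<- classify_vesicle(st$status,
                                           tally_genome(st$counts, reg))
          ci <<- ci + 1
        }
      }
      note(0)
      while (t < t_end && gen < opts$max_generations &&
             identical(st$status, "intact")) {
        st$t_birth <- t
        res <- simulate_vesicle(st, network, env, geom, consts, opts,
                                t_max_days = (t_end - t) / .DAY, xptr = xptr)
        note(res$t)
        t <- res$t
        if (res$fate == "divide") {
          gen <- gen + 1L
          keep <- if (identical(opts$keep_daughter_policy, "first")) 1L
                  else sample.int(2L, 1)
          st <- res$daughters[[keep]]
          st$lineage_id <- sprintf("r%d.v%d", r, v)
          div_rows[[length(div_rows) + 1]] <- data.frame(
            run = r, vesicle = v, generation = gen, t_div_days = t / .DAY,
            delta_t_days = (t - t_last_div) / .DAY,
            class_after = classify_vesicle("intact",
                                           tally_genome(st$counts, reg)),
            stringsAsFactors = FALSE)
          t_last_div <- t
        } else {
          st <- res$state
        }
      }
      note(t_end) # frozen state fills the remaining grid
      snap_rows[[length(snap_rows) + 1]] <- data.frame(
        run = r, vesicle = v, time_days = snaps_t, class = classes,
        stringsAsFactors = FALSE)
    }
  }
  divisions <- if (length(div_rows)) do.call(rbind, div_rows)
    else data.frame(run = integer(0), vesicle = integer(0),
                    generation = integer(0), t_div_days = numeric(0),
                    delta_t_days = numeric(0), class_after = character(0))
  structure(list(divisions = divisions,
                 snapshots = do.call(rbind, snap_rows),
                 n_entities = n_runs * vesicles_per_run,
                 seeds = seeds),
            class = "population_record")
}

#' @export
print.population_record <- function(x, ...) {
  cat(sprintf("<population record> %d entities, %d division events\n",
              x$n_entities, nrow(x$divisions)))
  invisible(x)
}

#' Per-generation division statistics
#'
#' Mean division time \eqn{<\Delta t_n>} (with its standard error) over all
#' entities that underwent an n-th division, and the percentage of tracked
#' entities dividing at that generation.
#'
#' @param record a [run_population()] record (or any data frame with
#'   columns \code{generation} and \code{delta_t_days}).
#' @param n_entities total tracked entities (taken from the record when
#'   available).
#' @return Data frame: generation, n, mean_delta_t_days, se_days,
#'   dividing_pct. Empty when no divisions were recorded.
#' @export
generation_statistics <- function(record, n_entities = NULL) {
  div <- if (inherits(record, "population_record")) record$divisions
         else record
  if (is.null(n_entities))
    n_entities <- if (inherits(record, "population_record"))
      record$n_entities else NA_integer_
  if (nrow(div) == 0)
    return(data.frame(generation = integer(0), n = integer(0),
                      mean_delta_t_days = numeric(0), se_days = numeric(0),
                      dividing_pct = numeric(0)))
  gens <- sort(unique(div$generation))
  out <- do.call(rbind, lapply(gens, function(g) {
    x <- div$delta_t_days[div$generation == g]
    data.frame(generation = g, n = length(x),
               mean_delta_t_days = mean(x),
               se_days = if (length(x) > 1) sd(x) / sqrt(length(x)) else NA,
               dividing_pct = 100 * length(x) / n_entities)
  }))
  out
}

#' Class composition of the population at a time
#'
#' Fractions of entities in each vesicle class at the latest census snapshot
#' at or before \code{t_days}; broken vesicles are included, and the
#' fractions sum to 1.
#'
#' @param record a [run_population()] record.
#' @param t_days snapshot time, days.
#' @return Named numeric vector over [vesicle_classes].
#' @export
composition_report <- function(record, t_days) {
  sn <- record$snapshots
  avail <- unique(sn$time_days[sn$time_days <= t_days])
  if (length(avail) == 0) stop("no snapshot at or before t = ", t_days)
  tt <- max(avail)
  cls <- factor(sn$class[sn$time_days == tt], levels = vesicle_classes)
  tab <- table(cls)
  setNames(as.vector(tab) / sum(tab), vesicle_classes)
}
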
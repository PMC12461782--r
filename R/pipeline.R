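## End-to-end pipeline over a ground-truth scenario or user inputs:
## equilibrium -> kinetics -> chelate decomposition -> mechanism, with one
## structured report carrying constants, rates, labels, uncertainties and
## the seeds that produced them.

#' Run the full analysis pipeline
#'
#' Executes the requested stages on a ground-truth scenario (or
#' user-supplied levels/trajectories) and collects every derived constant
#' into one report list that serialises cleanly to JSON.
#'
#' @param scenario a `ScenarioSpec` (e.g. from [presetScenario()]).
#' @param stages subset of `c("equilibrium", "kinetics", "chelate",
#'   "mechanism")`.
#' @param seed integer master seed; each stochastic stage derives its own
#'   sub-seed from it.
#' @param nReplicas,dt CTMC sampling design for the kinetics stage; `dt`
#'   defaults to a fifth of the fastest mean transition waiting time.
#' @param framesPerReplica frames saved per replica (default 20000, the
#'   replica design of a 2 ns run saved every 100 fs).  Steps too slow to
#'   produce transitions within this horizon are reported with rate 0 and
#'   the no-events flag rather than extended sampling.
#' @param kCenters microstate count for the MSM (default: twice the number
#'   of species).
#' @param lag MSM lag in frames (default 1).
#' @param mcSamples Monte Carlo draws for the pK uncertainties.
#' @param mechanismEvents planted events per mechanism for the mechanism
#'   stage.
#' @param out optional directory; when given, the report is written to
#'   `report.json` inside it.
#' @return A nested list (the report).
#' @export
runPipeline <- function(scenario,
                        stages = c("equilibrium", "kinetics", "chelate",
                                   "mechanism"),
                        seed = 1L, nReplicas = 100L, framesPerReplica = 20000L,
                        dt = NULL, kCenters = NULL, lag = 1L, mcSamples = 500L,
                        mechanismEvents = 10L, out = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  report <- list(seed = seed,
                 package = as.character(utils::packageVersion("chelkin")))
  eq <- NULL
  if ("equilibrium" %in% stages) {
    eq <- scenario$equilibrium
    lv <- scenario$levels
    mc <- if (any(lv@sigma > 0))
      pkUncertaintyMC(lv, scenario$comp, nSamples = mcSamples,
                      seed = seed + 1L)
    else list(mean = eq@pK, sd = rep(0, length(eq@pK)), rejected = 0)
    report$equilibrium <- list(
      species = eq@species,
      concentrations_mol_l = unname(eq@concentrations),
      free_ligand_mol_l = eq@freeLigand,
      pK = unname(eq@pK), pK_sd = unname(mc$sd),
      beta = unname(eq@beta),
      mc_rejected_fraction = mc$rejected, mc_seed = seed + 1L)
  }
  if (any(c("kinetics", "chelate") %in% stages)) {
    if (is.null(eq))
      stop("kinetics stage requires the equilibrium stage ([L] is needed)")
    if (is.na(scenario$comp@boxVolume))
      stop("kinetics stage requires a box volume in the composition")
    rates <- scenario$kPlus / scenario$gamma *
      (scenario$nLigTotal - scenario$comp@s[-length(scenario$comp@s)])
    fastest <- max(rates, scenario$kMinus)
    if (is.null(dt)) dt <- 0.2 / fastest
    tMax <- framesPerReplica * dt
    n <- length(scenario$levels@deltaG)
    if (is.null(kCenters)) kCenters <- 2L * n
    trajs <- simulateCTMC(scenario, nReplicas, tMax, dt, seed = seed + 2L)
    micro <- assignMicrostates(trajs, k = kCenters, seed = seed + 3L)
    micro <- estimateTransitionMatrix(micro, lag = lag)
    # one macrostate per coordination species actually sampled in both
    # directions; species outside the connected set drop out of the chain
    ligActive <- length(unique(round(micro@centers[micro@active, 1])))
    nMacro <- min(n, nrow(micro@transitionMatrix), ligActive)
    if (nMacro < 2L)
      stop("kinetics stage: fewer than two connected macrostates sampled; ",
           "increase the sampling horizon")
    macro <- pccaCoarseGrain(micro, nMacro = nMacro)
    est <- bayesianRateErrors(micro, macro, scenario$comp, eq,
                              nSamples = 50L, seed = seed + 4L)
    pkKin <- pkFromRates(est)
    report$kinetics <- list(
      step = est@step,
      k_forward_M_s = unname(est@kForward),
      k_backward_s = unname(est@kBackward),
      k_forward_ci = est@kForwardCI, k_backward_ci = est@kBackwardCI,
      pK_kinetic = unname(pkKin),
      gamma_l_mol = est@gamma, n_lig_eq = est@nLigEq,
      lag_frames = lag, dt_ps = micro@dt, seed = seed + 2L)
    if ("chelate" %in% stages && scenario$comp@denticity == 2L &&
        length(scenario$levels@deltaG) >= 3L) {
      twoStep <- tryCatch({
        br <- extractBidentateRates(macro, scenario$comp, eq)
        dec <- chelateDecompose(br)
        list(rates = unclass(br), log_K_or = dec$logKOr,
             log_K_cr = dec$logKCr, pK1 = dec$logK1,
             k_f = dec$kF, k_d = dec$kD,
             formation = dec$formationLimitedBy,
             dissociation = dec$dissociationLimitedBy)
      }, error = function(e) list(error = conditionMessage(e)))
      report$chelate <- twoStep
    }
  }
  if ("mechanism" %in% stages) {
    traj <- synthBindingTrajectory(
      mechanism = rep(c("dissociative", "associative"),
                      length.out = mechanismEvents),
      nEvents = mechanismEvents, seed = seed + 5L)
    ev <- detectBindingEvents(traj)
    ev <- classifyMechanism(traj, ev)
    report$mechanism <- list(summary = mechanismSummary(ev),
                             n_events = nrow(ev), seed = seed + 5L)
  }
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}
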
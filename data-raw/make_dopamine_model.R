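# Builds the SYNTHETIC presynaptic dopamine GMA network shipped at
# inst/extdata/dopamine_gma_synthetic.json.
#
# The network is a stand-in with the documented dimensions of the published
# presynaptic dopamine models (34 dependent metabolites, 68 power-law
# reactions, 3 external controls, 18 independent variables recorded as
# metadata) and the named pathway chemistry (TH, AADC, VMAT2, vesicular
# release, DAT reuptake, MAO, COMT, autoxidation to quinones, ROS/RNS
# chains). Rate constants are back-solved from a designed steady flux
# distribution so the designated basal state balances to machine precision.
# The kinetic parameters are NOT those of any published model; quantitative
# outputs are illustrative only.
#
# Run from the package root:  Rscript data-raw/make_dopamine_model.R

pkgload::load_all(".", quiet = TRUE)

species <- c(
  "TYR", "L-DOPA", "DA-i", "DA-v", "DOPA-Q", "NM", "DOPAC", "HVA",
  "DA-e", "3-MT", "DOPAL-e", "3-MT-e", "DOPAC-e", "HVA-e", "GSH",
  "DA-Q", "GSSG", "CYS-DA", "L-DOPA-e", "DA-NM", "DOPAC-Q-GS",
  "DOPAL-GS", "NO", "DOPAL", "DOPET", "DOPAC-Q", "O2-", "H2O2",
  "H2O2-e", "HO", "HO-NO2", "NO2", "NO2-TYR", "DOPET-e")

x_basal <- c(
  TYR = 120, `L-DOPA` = 8, `DA-i` = 100, `DA-v` = 500, `DOPA-Q` = 5,
  NM = 50, DOPAC = 20, HVA = 30, `DA-e` = 400, `3-MT` = 20,
  `DOPAL-e` = 10, `3-MT-e` = 8, `DOPAC-e` = 15, `HVA-e` = 25, GSH = 200,
  `DA-Q` = 10, GSSG = 20, `CYS-DA` = 4, `L-DOPA-e` = 3, `DA-NM` = 40,
  `DOPAC-Q-GS` = 4, `DOPAL-GS` = 3, NO = 3, DOPAL = 5, DOPET = 6,
  `DOPAC-Q` = 10, `O2-` = 5, H2O2 = 5, `H2O2-e` = 2, HO = 2,
  `HO-NO2` = 2, NO2 = 2, `NO2-TYR` = 1, `DOPET-e` = 3)

sp <- function(nm) match(nm, species)

# reaction table: index = a<k>; src, dst(s), routing weight (sources: flux),
# substrate kinetic order, named modifier orders, human label
rx <- list()
add <- function(k, src, dst, w, order = 0.6, modifier = NULL, label = "") {
  rx[[k]] <<- list(k = k, src = src, dst = dst, w = w, order = order,
                   modifier = modifier, label = label)
}

add(1,  "TYR",    "L-DOPA",              0.40, 0.55, label = "TH")
add(2,  "TYR",    "GSH",                 0.25, 0.60, label = "amino-acid pool to glutathione synthesis")
add(7,  "TYR",    character(0),          0.35, 0.65, label = "tyrosine utilisation/efflux")
add(4,  "L-DOPA", c("DOPA-Q", "O2-"),    0.06, 0.70, label = "L-DOPA autoxidation")
add(5,  "L-DOPA", "L-DOPA-e",            0.12, 0.60, label = "L-DOPA exchange")
add(6,  "L-DOPA", character(0),          0.07, 0.55, label = "L-DOPA other use")
add(8,  "L-DOPA", "DA-i",                0.75, 0.65, label = "AADC (DOPA decarboxylase)")
add(9,  "DOPA-Q", "NM",                  0.70, 0.60, label = "dopaquinone cyclisation to melanin")
add(10, "DOPA-Q", "CYS-DA",              0.30, 0.55, modifier = c(GSH = 0.3), label = "dopaquinone thiol conjugation")
add(11, "NM",     character(0),          1.00, 0.50, label = "neuromelanin turnover")
add(12, "DA-i",   "DA-v",                0.30, 0.75, label = "VMAT2 vesicular packaging")
add(13, "DA-e",   "DA-i",                0.30, 0.70, label = "DAT reuptake")
add(14, "DA-v",   "DA-e",                1.00, 0.60, label = "vesicular release")
add(15, "DA-i",   c("DOPAL", "H2O2"),    0.27, 0.70, label = "MAO (intracellular)")
add(16, "DA-i",   c("DA-Q", "O2-"),      0.09, 0.65, label = "dopamine autoxidation")
add(17, "DA-i",   "3-MT",                0.14, 0.60, label = "COMT (intracellular)")
add(20, "DA-i",   character(0),          0.20, 0.55, label = "dopamine other use")
add(22, "DA-e",   "3-MT",                0.27, 0.65, label = "COMT (extracellular)")
add(23, "3-MT",   c("HVA", "H2O2"),      0.70, 0.65, label = "MAO on 3-MT")
add(24, "DA-e",   c("DOPAL-e", "H2O2-e"),0.32, 0.70, label = "MAO (extracellular)")
add(25, "DOPAL",  "DOPAC",               0.60, 0.60, label = "ALDH")
add(26, "DOPAC",  "HVA",                 0.55, 0.60, label = "COMT on DOPAC")
add(27, "DOPAC",  "DOPAC-e",             0.25, 0.55, label = "DOPAC export")
add(28, "DOPAC",  c("DOPAC-Q", "O2-"),   0.08, 0.65, label = "DOPAC autoxidation")
add(29, "DOPAC",  character(0),          0.12, 0.55, label = "DOPAC other use")
add(30, "HVA",    "HVA-e",               0.80, 0.55, label = "HVA export")
add(31, "HVA",    character(0),          0.20, 0.55, label = "HVA other use")
add(32, "DA-e",   character(0),          0.11, 0.00, label = "saturated extracellular clearance (zero order)")
add(34, "3-MT",   "3-MT-e",              0.20, 0.55, label = "3-MT export")
add(35, "3-MT",   character(0),          0.10, 0.55, label = "3-MT other use")
add(36, "DOPAL-e", character(0),         1.00, 0.55, label = "extracellular DOPAL clearance")
add(37, "3-MT-e", character(0),          1.00, 0.55, label = "extracellular 3-MT clearance")
add(38, "DOPAC-e", character(0),         1.00, 0.55, label = "extracellular DOPAC clearance")
add(39, "HVA-e",  character(0),          1.00, 0.55, label = "extracellular HVA clearance")
add(40, "DOPAL",  "DOPET",               0.15, 0.55, label = "aldehyde reduction (ADH)")
add(41, "GSSG",   "GSH",                 1.00, 0.60, label = "glutathione reductase")
add(42, "GSH",    "GSSG",                0.60, 0.60, modifier = c(H2O2 = 0.3), label = "glutathione peroxidase cycle")
add(43, "GSH",    character(0),          0.40, 0.55, label = "glutathione other use")
add(45, "DA-Q",   "CYS-DA",              0.50, 0.60, modifier = c(GSH = 0.3), label = "dopamine quinone thiol conjugation")
add(46, "DA-Q",   "DA-NM",               0.30, 0.60, label = "quinone polymerisation")
add(47, "DA-Q",   character(0),          0.20, 0.55, label = "quinone other fate")
add(48, "CYS-DA", character(0),          1.00, 0.55, label = "cysteinyl-dopamine clearance")
add(49, "L-DOPA-e", character(0),        1.00, 0.55, label = "extracellular L-DOPA clearance")
add(50, "DA-NM",  character(0),          1.00, 0.50, label = "melanin turnover")
add(51, NA,       "NO",                  1.00, 0.00, label = "NO synthesis (nNOS, constant)")
add(52, "NO",     "HO-NO2",              0.70, 0.60, modifier = c(`O2-` = 0.4), label = "peroxynitrite formation")
add(54, "NO",     character(0),          0.30, 0.55, label = "NO other fate")
add(55, "DOPAL",  "DOPAL-GS",            0.15, 0.55, modifier = c(GSH = 0.3), label = "DOPAL thiol adduct")
add(68, "DOPAL",  character(0),          0.10, 0.55, label = "DOPAL other fate")
add(56, "O2-",    "H2O2",                0.70, 0.70, label = "superoxide dismutase")
add(57, "O2-",    character(0),          0.30, 0.55, label = "superoxide other fate")
add(58, "H2O2",   character(0),          0.55, 0.65, label = "catalase/GPx removal")
add(59, "H2O2",   "HO",                  0.15, 0.60, label = "Fenton reaction (iron absorbed)")
add(60, "H2O2",   "H2O2-e",              0.30, 0.55, label = "H2O2 membrane diffusion")
add(61, "H2O2-e", character(0),          1.00, 0.55, label = "extracellular H2O2 removal")
add(62, "HO",     character(0),          1.00, 0.55, label = "hydroxyl radical quenching")
add(63, "HO-NO2", "NO2",                 0.60, 0.60, label = "peroxynitrite decomposition")
add(64, "HO-NO2", character(0),          0.40, 0.55, label = "peroxynitrite other fate")
add(65, "NO2",    "NO2-TYR",             0.30, 0.55, label = "tyrosine nitration")
add(66, "NO2",    character(0),          0.70, 0.55, label = "NO2 other fate")
add(67, "NO2-TYR", character(0),         1.00, 0.55, label = "nitrotyrosine clearance")
add(3,  "DOPAC-Q", "DOPAC-Q-GS",         0.50, 0.55, modifier = c(GSH = 0.3), label = "DOPAC quinone thiol conjugation")
add(18, "DOPAC-Q", character(0),         0.50, 0.55, label = "DOPAC quinone other fate")
add(19, "DOPAC-Q-GS", character(0),      1.00, 0.55, label = "conjugate clearance")
add(21, "DOPAL-GS", character(0),        1.00, 0.55, label = "adduct clearance")
add(33, "DOPET",  "DOPET-e",             0.50, 0.55, label = "DOPET export")
add(44, "DOPET",  character(0),          0.50, 0.55, label = "DOPET other use")
add(53, "DOPET-e", character(0),         1.00, 0.55, label = "extracellular DOPET clearance")

rx <- rx[order(vapply(rx, function(e) e$k, numeric(1)))]
stopifnot(length(rx) == 68,
          identical(vapply(rx, function(e) e$k, numeric(1)), as.numeric(1:68)))

ed <- data.frame(src = vapply(rx, function(e)
  if (is.na(e$src[1])) NA_integer_ else as.integer(sp(e$src)), integer(1)))
ed$dst <- lapply(rx, function(e) as.integer(vapply(e$dst, sp, numeric(1))))
ed$weight <- vapply(rx, function(e) e$w, numeric(1))
ed$order <- vapply(rx, function(e) e$order, numeric(1))
ed$modifier <- lapply(rx, function(e) e$modifier)
ed$name <- paste0("a", 1:68)

# per-species outgoing weights must each sum to 1
wsum <- tapply(ed$weight[!is.na(ed$src)], ed$src[!is.na(ed$src)], sum)
stopifnot(all(abs(wsum - 1) < 1e-12))

# external controls: tyrosine intake u_t (basal 10 flux units), exogenous
# L-DOPA u_l (basal 2.2; the DOPA-decarboxylase bypass that keeps
# extracellular dopamine nonzero under complete TH deficiency), dopamine
# dosing u_d (basal 0)
u_basal <- c(u_t = 10, u_l = 2.2, u_d = 0)
ext <- numeric(34)
ext[sp("TYR")] <- u_basal[["u_t"]]
ext[sp("L-DOPA")] <- u_basal[["u_l"]]

routed <- fmdd:::route_fluxes(34, ed, ext)

controls <- list(names = names(u_basal),
                 into = c(sp("TYR"), sp("L-DOPA"), sp("DA-i")),
                 basal = unname(u_basal))

independents <- lapply(
  c("O2", "SAM", "SAH", "BH4", "NAD", "NADH", "Fe2", "Tyrosinase", "GPx",
    "Catalase", "nNOS", "Arg", "Cys", "SULT", "ALDH", "ADH", "MAO-protein",
    "COMT-protein"),
  function(nm) list(name = nm, value = 1.0))

meta <- list(
  title = "Synthetic presynaptic dopamine GMA network (stand-in)",
  synthetic = TRUE,
  note = paste("Topology and dimensions follow the presynaptic dopamine",
               "pathway; rate constants are back-solved from a designed",
               "basal flux distribution and are NOT the parameters of any",
               "published model."),
  aliases = list(TH = "a1", AADC = "a8", VMAT2 = "a12", DAT = "a13",
                 RELEASE = "a14", MAO = "a15", `MAO-3MT` = "a23",
                 `MAO-e` = "a24", COMT = "a17", `COMT-e` = "a22",
                 `COMT-DOPAC` = "a26"),
  therapeutic = "DA-e",
  toxic = c("DOPA-Q", "3-MT", "DOPAL-e", "DA-Q", "DOPAL", "DOPAC-Q"),
  ros = c("O2-", "H2O2", "H2O2-e", "HO"),
  rns = c("HO-NO2", "NO2"),
  independents = independents)

net <- fmdd:::gma_from_fluxes(species, unname(x_basal[species]), ed,
                              routed$flux, controls, meta = meta)
stopifnot(net$consistent)

# sanity: qualitative disease regimes the scenarios rely on
chk <- function(delta, reaction) {
  st <- solve_steady_state(net, apply_deficiency(net, reaction, delta))
  stopifnot(st$converged)
  st
}
hs <- solve_steady_state(net)
vm <- vapply(c(50, 70, 90, 95, 100), function(d)
  chk(d, "a12")$x[["DA-e"]], numeric(1))
cat("DA-e under VMAT2 deficiency 50/70/90/95/100:", round(vm, 4), "\n")
stopifnot(all(diff(vm) < 1e-9))
th <- chk(100, "a1")
cat("DA-e under complete TH deficiency:", round(th$x[["DA-e"]], 2), "\n")
stopifnot(th$x[["DA-e"]] > 1)
z95 <- chk(95, "a12")
cat("effectively zero at VM95:", z95$effectively_zero[["DA-e"]], "\n")

write_gma_model(net, "inst/extdata/dopamine_gma_synthetic.json")
cat("wrote inst/extdata/dopamine_gma_synthetic.json\n")
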
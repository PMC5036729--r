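---
title: "Cross-ratio intuitionistic fuzzy decision analysis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-ratio intuitionistic fuzzy decision analysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icrdm)
```

## The model

An intuitionistic fuzzy value (IFV) is a pair $(\xi, \eta)$ of membership
and non-membership degrees with $\xi + \eta \le 1$; the residual
$1 - \xi - \eta$ is the decision maker's hesitancy. `icrdm` works with the
*cross-ratio* subclass, where both components lie strictly inside $(0, 1)$
and the natural calculus is the odds transform

$$u = \frac{x}{1 - x}, \qquad x = \frac{u}{1 + u}.$$

Under this transform the package's four operations become elementary odds
arithmetic:

| operation | probability form | odds form |
|---|---|---|
| $\alpha_1 \oplus \alpha_2$ | $\left(\frac{\xi_1+\xi_2-2\xi_1\xi_2}{1-\xi_1\xi_2},\ \frac{\eta_1\eta_2}{\eta_1+\eta_2-\eta_1\eta_2}\right)$ | odds add; non-membership odds combine harmonically |
| $\alpha_1 \otimes \alpha_2$ | both components through $\frac{xy}{xy+(1-x)(1-y)}$ | odds multiply |
| $\lambda \alpha$ | $\left(\frac{\lambda\xi}{\lambda\xi+1-\xi},\ \frac{\eta}{\eta+\lambda(1-\eta)}\right)$ | $(\lambda u_\xi,\ u_\eta/\lambda)$ |
| $\alpha^\lambda$ | $\left(\frac{\xi^\lambda}{\xi^\lambda+(1-\xi)^\lambda},\ \frac{\eta^\lambda}{\eta^\lambda+(1-\eta)^\lambda}\right)$ | odds to the power $\lambda$ |

$\otimes$ is the and-like representable cross-ratio (ALRCR) uninorm with
neutral element $0.5$, applied *symmetrically* to both components. The
symmetric treatment is deliberate: it keeps the algebra closed on
$(0,1)$-valued IFVs, makes $(0.5, 0.5)$ a true identity, and is the choice
that reproduces the package's embedded case study. (In the source
literature the non-membership component of the product is garbled by
typography; the symmetric uninorm is the reading consistent with that
text's own gloss and with every number it prints.)

Ranking uses two odds functionals: the **score**
$S = \operatorname{logistic}\!\big(\tfrac{1}{2}\log(u_\xi/u_\eta)\big)
= \frac{\sqrt{\xi(1-\eta)}}{\sqrt{\xi(1-\eta)} + \sqrt{(1-\xi)\eta}}$
and the **accuracy** $H = u_\xi u_\eta \in (0, 1]$, with hesitation margin
$\pi = 1 - H$. Values compare by score, then accuracy; equal score and
accuracy imply equal components.

### The two score variants

The literature this package implements states the score as the odds-ratio
logistic $S_{\mathrm{eq4}} = \frac{\xi(1-\eta)}{\xi(1-\eta)+(1-\xi)\eta}$
but *uses* values that only the square-root (geometric) form reproduces:
$S((0.9, 0.1))$ is quoted as $0.9$, which is the geometric value, where
the literal formula gives $81/82 \approx 0.9878$; the same holds for every
case-study score. Both variants are strictly increasing in the odds ratio
$u_\xi/u_\eta$, so they induce **identical rankings**; only the reported
numbers differ. `icrdm` therefore defaults to `variant = "geometric"`
everywhere and retains `"eq4"` as an explicit option, and the test suite
pins both the agreement of the geometric variant with the published
figures and the disagreement of the literal one — a documented design
decision, not a silent fix.

## Aggregation

The intuitionistic cross-ratio weighted geometric operator is
$\mathrm{ICRWG}_\omega(\alpha_1, \ldots, \alpha_m) = \bigotimes_i
\alpha_i^{\omega_i}$, i.e. the componentwise weighted geometric mean of
odds. It is idempotent, monotone, bounded, and closed on the rating scale
(below). Internally it is computed as a weighted arithmetic mean of
log-odds — analytically identical to the printed product form, but immune
to underflow for long inputs. Zero weights are allowed
($\alpha^0 = (0.5, 0.5)$, the neutral element), so a criterion can be
switched off without re-indexing.

Two published baselines, the Xu–Yager IFWG and the Einstein weighted
geometric operator, are provided under an explicit `baseline_` prefix for
discrimination comparisons only; the decision procedure never calls them.
On the worked example — three ratings $(0.9, 0.1)$ against one
$(0.1, 0.9)$ — they yield memberships $0.5196$ and $0.5836$, barely above
indifference, where the cross-ratio mean gives $(0.75, 0.25)$.

## The rating scale and preference relations

Ratings live on a bounded bipolar $0.1$–$0.9$ scale related to Saaty's
$1$–$9$ scale by $r \mapsto r/(1+r)$: $9 \mapsto 0.9$, $1 \mapsto 0.5$,
$1/9 \mapsto 0.1$, with $f(1/r) = 1 - f(r)$. The scale bound is a
*validation mode*, not a constraint of the algebra: `scale_mode = TRUE`
(the default for decision problems) checks IPR entries against
$[0.1, 0.9]$; the algebra itself is happy on all of $(0, 1)$.

An intuitionistic preference relation (IPR) is a square matrix of IFVs
with diagonal $(0.5, 0.5)$ and complement-transposed reciprocity
$r_{ji} = (\eta_{ij}, \xi_{ij})$. `validate_ipr()` reports every violated
cell rather than repairing it; `ipr(..., fix_reciprocal = TRUE)` rebuilds
the lower triangle when repair is wanted. Local priorities are the
row-wise ICRWG mean *including the diagonal* — the convention the embedded
case study requires.

## The decision procedure

1. State alternatives, criteria, criterion weights $\omega$ (reals summing
   to 1), and one IPR per criterion.
2. Collapse each IPR row-wise to local priorities
   $\tilde\beta_{il}$.
3. Assemble the $n \times m$ decision matrix.
4. Fuse each alternative's row with $\mathrm{ICRWG}_\omega$ to the overall
   priority $\tilde\beta_{x_i}$.
5. Score and accuracy per alternative.
6. Rank in decreasing order; exact ties (equal score *and* accuracy) are
   grouped, reported as tie sets, and ordered by input position rather
   than broken arbitrarily.

```{r}
res <- solve_decision(mwdms_problem())
res
```

The embedded problem selects among five medical-waste disposal methods
(incineration, autoclave, microwave, sterilization, other treatments)
under technical, economic and social/environmental criteria with weights
$(0.4, 0.35, 0.25)$; the pipeline above reproduces its published decision
matrix, overall priorities, scores and the ranking
$x_1 > x_2 > x_5 > x_3 > x_4$ to four decimals. Three last-digit
discrepancies against the printed source are known and deliberate: the
package computes at full precision, while the source rounded an
intermediate (its $x_4$ non-membership $0.6217$ recomputes to $0.6218$,
and two scores shift by one unit in the fourth decimal). The regression
suite asserts the recomputed values.

## Numerical choices

* **Log-odds internals.** All operations and aggregates evaluate via
  `qlogis`/`plogis`; results are nudged back into the open interval by
  $10^{-15}$ where `plogis` saturates. Equality of values is tested at
  absolute tolerance $10^{-9}$ per component; comparisons
  (`ifv_compare()`) act on log-odds quantities at relative tolerance
  $10^{-10}$, which makes the order independent of the score variant and
  of double rounding through probability space.
* **Validation.** Components within $10^{-12}$ of 0 or 1 are rejected;
  `clamp = TRUE` instead clamps file input into
  $[10^{-9}, 1 - 10^{-9}]$. The sum constraint carries a $10^{-9}$
  tolerance. Fractions in input cells (`"5/8,1/5"`) are parsed as
  numerator over denominator, so fixtures carry more precision than their
  4-decimal printed form.
* **Weights.** Strict mode requires the sum to be 1 within $10^{-6}$;
  permissive mode renormalises. $\lambda = 0$ powers are defined as the
  neutral element.

## What the random generator emulates — and what it does not

`random_ipr()` draws upper-triangle memberships uniformly on
$[0.1, 0.9]$ and non-memberships uniformly on
$[0.1, \min(0.9, 1-\xi)]$, then fills the reciprocal half and the
diagonal by construction. It emulates *structurally valid* expert input:
every generated relation passes validation, and closure properties
(priorities staying on the scale) hold by theorem. It does **not** emulate
a coherent decision maker — there is no consistency structure across
triads, no correlation between criteria, and no realistic hesitancy
profile. A green property test therefore establishes algebraic
correctness on the stated domain, not behavioural validity of any
elicitation; consistency indices and repair are out of scope by design.

## Known limitations

* Two hierarchy levels only; no group decision making, no weight
  elicitation from a criteria-level comparison matrix, no sensitivity
  analysis over weights.
* No consistency checking or missing-entry estimation for IPRs.
* The Einstein product appears only as an aggregation baseline, not as a
  pairwise algebra.
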
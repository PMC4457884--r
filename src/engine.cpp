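// Particle engine: hexagonal surface lattice, excluded-volume random walks,
// collision-probability bimolecular reactions, and an event-driven stochastic
// scheduler for first-order and neighbour-dependent dissociation reactions.
//
// Geometry: a W x H sheet of voxels on a triangular (hexagonally packed)
// lattice with periodic boundaries. Row spacing is sqrt(3)*r, column spacing
// 2*r, odd rows shifted by +r; every voxel has 6 equidistant neighbours at
// distance 2*r. H must be even for the periodic wrap to be consistent.
//
// All reaction propensities are piecewise constant between conversion events,
// so the direct-method scheduler (resampled after every conversion) is exact.
//
// Hot-path layout: occupancy and filament voxels are mirrored in bitmasks
// (one bit per voxel, L1-resident) so the common case of a walk attempt into
// a vacant voxel touches almost no scattered memory; the molecule-id
// occupancy array is only read when a collision actually happens. Unwrapped
// positions are accumulated as integer lattice displacements (units of r
// along x and sqrt(3)*r along y).

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

// --- xoshiro256** RNG (deterministic, seed-derived, independent of R's) ---
struct Rng {
  uint64_t s[4];
  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t sd) {
    uint64_t x = sd;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    uint64_t r = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // unbiased-enough bounded draw via multiply-shift (no division)
  inline uint32_t below(uint32_t n) {
    return (uint32_t)(((next() >> 32) * (uint64_t)n) >> 32);
  }
  inline double expdev() { double u; do { u = unif(); } while (u <= 0.0); return -std::log(u); }
};

struct FirstOrder { int from, to; double k; int tag; };
struct Dissoc    { int from, to; int uniform; double par; int tag; double rate[7]; }; // par: base (uniform=0) or rate (uniform=1)
struct ColRule   { double p; int prodMover, prodOcc; int tag; };

struct WalkClock { double tau; double next; std::vector<int> specs; long nmol; };

// displacement per direction in lattice units (x in r, y in sqrt(3)*r)
static const int DU[6] = { 2, -2, 1, -1, 1, -1 };
static const int DW[6] = { 0,  0, 1,  1, -1, -1 };
// column offset per (row parity, direction); row offset per direction
static const int DI[2][6] = { { 1, -1, 0, -1, 0, -1 }, { 1, -1, 1, 0, 1, 0 } };
static const int DJ[6] = { 0, 0, 1, 1, -1, -1 };

struct Engine {
  // lattice
  int W, H, nvox;
  double rv;                       // voxel radius (m)
  // occupancy / molecules
  std::vector<int32_t> occ;        // voxel -> molecule id (-1 empty)
  std::vector<uint64_t> occBit;    // occupancy bitmask
  std::vector<uint64_t> filBit;    // filament bitmask
  std::vector<int32_t> mcol, mrow; // molecule lattice coordinates
  std::vector<int32_t> upos;       // 2 per molecule: unwrapped (u, w) lattice units
  std::vector<int32_t> mspec;
  std::vector<uint32_t> stamp;     // last walk tick per molecule
  std::vector<uint8_t> nbound;     // neighbouring cluster-state molecule count
  // species
  int nspec;
  std::vector<std::string> sname;
  std::vector<double> stau;        // walk interval (s); <=0 immobile
  std::vector<uint8_t> sclust;     // cluster-state flag
  std::vector<int> clockOf;        // species -> walk clock (-1 immobile)
  std::vector<int> dissOf;         // species -> dissociation rule (-1 none)
  std::vector<std::vector<int32_t>> slist; // per-species molecule list
  std::vector<int32_t> mpos;       // molecule -> index in its species list
  // rules
  std::vector<ColRule> col;        // nspec*nspec
  std::vector<FirstOrder> fo;
  std::vector<Dissoc> diss;
  std::vector<std::vector<std::vector<int32_t>>> bucket; // per diss rule, per n=0..6
  std::vector<int32_t> bpos;       // molecule -> index in its bucket
  // cluster adjacency
  std::vector<int16_t> nadj;       // voxel -> # neighbour voxels holding cluster-state molecules
  bool meshOn = false;
  double gapp = 0.0;
  // clocks / scheduler
  std::vector<WalkClock> clocks;
  double t = 0.0, t_ssa = INF;
  bool ssaDirty = true;
  uint32_t tick = 0;
  // stats
  std::vector<double> colAttempt, colFire; // nspec*nspec
  std::vector<double> eventCount;          // per tag (size 64)
  // event log
  bool logOn = false; double log0 = 0, log1 = 0; size_t logMax = 0;
  std::vector<double> logT; std::vector<int> logTag;
  // traces
  bool traceOn = false; double trace_dt = 0, t_trace = INF;
  std::vector<int32_t> tracked;
  std::vector<double> traceBuf;
  std::vector<double> traceTimes;
  Rng rng;

  Engine(int W_, int H_, double rv_, uint64_t seed) : W(W_), H(H_), rv(rv_) {
    nvox = W * H;
    occ.assign(nvox, -1);
    occBit.assign((nvox + 63) / 64, 0);
    filBit.assign((nvox + 63) / 64, 0);
    nadj.assign(nvox, 0);
    nspec = 0;
    rng.seed(seed);
    eventCount.assign(64, 0.0);
  }

  inline bool bitGet(const std::vector<uint64_t> &b, int v) const {
    return (b[v >> 6] >> (v & 63)) & 1ULL;
  }
  inline void bitSet(std::vector<uint64_t> &b, int v) { b[v >> 6] |= (1ULL << (v & 63)); }
  inline void bitClr(std::vector<uint64_t> &b, int v) { b[v >> 6] &= ~(1ULL << (v & 63)); }

  // directions: 0=E 1=W 2=NE 3=NW 4=SE 5=SW (fixed geometric meaning)
  inline void neighborCoords(int i, int j, int d, int &i2, int &j2) const {
    i2 = i + DI[j & 1][d];
    if (i2 < 0) i2 += W; else if (i2 >= W) i2 -= W;
    j2 = j + DJ[d];
    if (j2 < 0) j2 += H; else if (j2 >= H) j2 -= H;
  }
  inline int neighborOf(int v, int d) const {
    int j = v / W, i = v - j * W, i2, j2;
    neighborCoords(i, j, d, i2, j2);
    return j2 * W + i2;
  }

  double voxX(int v) const { int j = v / W, i = v % W; return 2.0 * rv * i + (j & 1) * rv; }
  double voxY(int v) const { int j = v / W; return std::sqrt(3.0) * rv * j; }

  int addSpecies(const std::string &nm, double tau, bool clust) {
    sname.push_back(nm); stau.push_back(tau); sclust.push_back(clust ? 1 : 0);
    dissOf.push_back(-1);
    slist.push_back({});
    int s = nspec++;
    int ck = -1;
    if (tau > 0) {
      for (size_t i = 0; i < clocks.size(); ++i)
        if (std::abs(clocks[i].tau - tau) < 1e-18) { ck = (int)i; break; }
      if (ck < 0) { clocks.push_back({tau, INF, {}, 0}); ck = (int)clocks.size() - 1; }
      clocks[ck].specs.push_back(s);
    }
    clockOf.push_back(ck);
    std::vector<ColRule> nc(nspec * (size_t)nspec, ColRule{0.0, -1, -1, -1});
    for (int a = 0; a < nspec - 1; ++a)
      for (int b = 0; b < nspec - 1; ++b) nc[a * (size_t)nspec + b] = col[a * (size_t)(nspec - 1) + b];
    col = nc;
    colAttempt.assign(nspec * (size_t)nspec, 0.0);
    colFire.assign(nspec * (size_t)nspec, 0.0);
    return s;
  }

  void setCollision(int a, int b, int pa, int pb, double p, int tag) {
    col[a * (size_t)nspec + b] = ColRule{p, pa, pb, tag};
    if (a != b) col[b * (size_t)nspec + a] = ColRule{p, pb, pa, tag};
  }

  void addFirstOrder(int from, int to, double k, int tag) { fo.push_back({from, to, k, tag}); }

  void addDissoc(int from, int to, bool uniform, double par, int tag) {
    Dissoc d{from, to, uniform ? 1 : 0, par, tag, {0, 0, 0, 0, 0, 0, 0}};
    for (int n = 0; n <= 6; ++n)
      d.rate[n] = uniform ? par : std::pow(par, 6 - n);
    diss.push_back(d);
    dissOf[from] = (int)diss.size() - 1;
    bucket.push_back(std::vector<std::vector<int32_t>>(7));
  }

  inline double dissRate(const Dissoc &d, int n) const { return d.rate[n]; }

  void wake(int ck) {
    if (ck >= 0 && clocks[ck].nmol == 0) clocks[ck].next = t + clocks[ck].tau;
  }

  int newMolecule(int spec, int v) {
    int id = (int)mspec.size();
    int j = v / W, i = v - j * W;
    mcol.push_back(i); mrow.push_back(j);
    upos.push_back(2 * i + (j & 1)); upos.push_back(j);
    mspec.push_back(spec);
    stamp.push_back(0); nbound.push_back(0); mpos.push_back(-1); bpos.push_back(-1);
    occ[v] = id; bitSet(occBit, v);
    wake(clockOf[spec]);
    mpos[id] = (int)slist[spec].size();
    slist[spec].push_back(id);
    if (clockOf[spec] >= 0) clocks[clockOf[spec]].nmol++;
    if (sclust[spec]) clusterGain(id, v);
    ssaDirty = true;
    return id;
  }

  void clusterGain(int m, int v) {
    nbound[m] = (uint8_t)nadj[v];
    int r = dissOf[mspec[m]];
    if (r >= 0) { bpos[m] = (int)bucket[r][nbound[m]].size(); bucket[r][nbound[m]].push_back(m); }
    for (int d = 0; d < 6; ++d) {
      int w = neighborOf(v, d);
      nadj[w]++;
      int om = occ[w];
      if (om >= 0 && sclust[mspec[om]] && om != m) bumpNeighbour(om, +1);
    }
  }

  void clusterLose(int m, int v) {
    int r = dissOf[mspec[m]];
    if (r >= 0) bucketRemove(r, m);
    for (int d = 0; d < 6; ++d) {
      int w = neighborOf(v, d);
      nadj[w]--;
      int om = occ[w];
      if (om >= 0 && sclust[mspec[om]] && om != m) bumpNeighbour(om, -1);
    }
  }

  void bucketRemove(int r, int m) {
    std::vector<int32_t> &bk = bucket[r][nbound[m]];
    int p = bpos[m];
    int last = bk.back(); bk[p] = last; bpos[last] = p; bk.pop_back(); bpos[m] = -1;
  }

  void bumpNeighbour(int om, int delta) {
    int r = dissOf[mspec[om]];
    if (r >= 0) bucketRemove(r, om);
    nbound[om] = (uint8_t)(nbound[om] + delta);
    if (r >= 0) { bpos[om] = (int)bucket[r][nbound[om]].size(); bucket[r][nbound[om]].push_back(om); }
  }

  void convert(int m, int snew) {
    int sold = mspec[m];
    if (sold == snew) return;
    int v = mrow[m] * W + mcol[m];
    if (sclust[sold] && !sclust[snew]) clusterLose(m, v);
    std::vector<int32_t> &lo = slist[sold];
    int p = mpos[m], last = lo.back();
    lo[p] = last; mpos[last] = p; lo.pop_back();
    mspec[m] = snew;
    mpos[m] = (int)slist[snew].size();
    slist[snew].push_back(m);
    int co = clockOf[sold], cn = clockOf[snew];
    if (co != cn) {
      if (co >= 0) clocks[co].nmol--;
      if (cn >= 0) { wake(cn); clocks[cn].nmol++; }
    }
    if (!sclust[sold] && sclust[snew]) clusterGain(m, v);
    ssaDirty = true;
  }

  inline void logEvent(int tag) {
    if (tag >= 0 && tag < (int)eventCount.size()) eventCount[tag] += 1.0;
    if (logOn && t >= log0 && t <= log1 && logT.size() < logMax) {
      logT.push_back(t); logTag.push_back(tag);
    }
  }

  inline void walkOne(int m, int s) {
    int i = mcol[m], j = mrow[m];
    uint64_t rnd = rng.next();
    int d = (int)(((rnd >> 32) * 6ULL) >> 32);
    int i2, j2;
    neighborCoords(i, j, d, i2, j2);
    int to = j2 * W + i2;
    if (meshOn && bitGet(filBit, to)) {
      // fence crossing: with gap probability, jump across the filament voxel
      if (gapp > 0 && rng.unif() < gapp) {
        int i3, j3;
        neighborCoords(i2, j2, d, i3, j3);
        int b = j3 * W + i3;
        if (!bitGet(filBit, b) && !bitGet(occBit, b)) {
          int v = j * W + i;
          occ[v] = -1; bitClr(occBit, v);
          occ[b] = m; bitSet(occBit, b);
          mcol[m] = i3; mrow[m] = j3;
          upos[2 * m] += 2 * DU[d]; upos[2 * m + 1] += 2 * DW[d];
        }
      }
      return;
    }
    if (!bitGet(occBit, to)) {
      int v = j * W + i;
      occ[v] = -1; bitClr(occBit, v);
      occ[to] = m; bitSet(occBit, to);
      mcol[m] = i2; mrow[m] = j2;
      upos[2 * m] += DU[d]; upos[2 * m + 1] += DW[d];
      return;
    }
    int o = occ[to];
    int so = mspec[o];
    const ColRule &cr = col[s * (size_t)nspec + so];
    colAttempt[s * (size_t)nspec + so] += 1.0;
    if (cr.p > 0 && (cr.p >= 1.0 || rng.unif() < cr.p)) {
      colFire[s * (size_t)nspec + so] += 1.0;
      convert(m, cr.prodMover);
      convert(o, cr.prodOcc);
      logEvent(cr.tag);
    }
  }

  void fireWalkClock(int ci) {
    WalkClock &c = clocks[ci];
    if (c.nmol == 0) { c.next = INF; return; }
    ++tick;
    for (int si : c.specs) {
      std::vector<int32_t> &lst = slist[si];
      for (int i = (int)lst.size() - 1; i >= 0; --i) {
        if (i >= (int)lst.size()) continue; // list shrank during iteration
        int m = lst[i];
        if (stamp[m] == tick) continue;
        stamp[m] = tick;
        if (mspec[m] != si) continue;
        walkOne(m, si);
      }
    }
    c.next += c.tau;
  }

  std::vector<double> propCum; // cached cumulative propensities (valid while !ssaDirty)
  double propTot = 0.0;

  void totalPropensity() {
    propCum.resize(fo.size() + diss.size());
    double tot = 0.0;
    size_t c = 0;
    for (const FirstOrder &r : fo) { tot += r.k * slist[r.from].size(); propCum[c++] = tot; }
    for (size_t ri = 0; ri < diss.size(); ++ri) {
      double a = 0.0;
      for (int n = 0; n <= 6; ++n) a += bucket[ri][n].size() * dissRate(diss[ri], n);
      tot += a; propCum[c++] = tot;
    }
    propTot = tot;
  }

  void resampleSSA() {
    totalPropensity();
    t_ssa = (propTot > 0) ? t + rng.expdev() / propTot : INF;
    ssaDirty = false;
  }

  void fireSSA() {
    // propensities are unchanged since the last resample
    const std::vector<double> &cum = propCum;
    double tot = propTot;
    if (tot <= 0) { ssaDirty = true; return; }
    double u = rng.unif() * tot;
    size_t ch = 0;
    while (ch < cum.size() && u > cum[ch]) ++ch;
    if (ch >= cum.size()) ch = cum.size() - 1;
    if (ch < fo.size()) {
      const FirstOrder &r = fo[ch];
      std::vector<int32_t> &lst = slist[r.from];
      if (!lst.empty()) {
        int m = lst[rng.below((uint32_t)lst.size())];
        convert(m, r.to);
        logEvent(r.tag);
      }
    } else {
      size_t ri = ch - fo.size();
      const Dissoc &dr = diss[ri];
      double a = cum[ch] - (ch > 0 ? cum[ch - 1] : 0.0);
      double w = rng.unif() * a;
      int n = 0; double acc = 0.0;
      for (; n <= 6; ++n) { acc += bucket[ri][n].size() * dissRate(dr, n); if (w <= acc) break; }
      if (n > 6) n = 6;
      while (n >= 0 && bucket[ri][n].empty()) --n;
      if (n >= 0) {
        std::vector<int32_t> &bk = bucket[ri][n];
        int m = bk[rng.below((uint32_t)bk.size())];
        convert(m, dr.to);
        logEvent(dr.tag);
      }
    }
    ssaDirty = true;
  }

  void sampleTrace() {
    const double sy = std::sqrt(3.0) * rv;
    traceTimes.push_back(t);
    for (int m : tracked) {
      traceBuf.push_back(upos[2 * m] * rv);
      traceBuf.push_back(upos[2 * m + 1] * sy);
    }
    t_trace += trace_dt;
  }

  void run(double dur) {
    double tend = t + dur;
    for (;;) {
      if (ssaDirty) resampleSSA();
      double tn = tend; int kind = -1, idx = -1;
      for (size_t i = 0; i < clocks.size(); ++i)
        if (clocks[i].next < tn) { tn = clocks[i].next; kind = 0; idx = (int)i; }
      if (t_ssa < tn) { tn = t_ssa; kind = 1; }
      if (traceOn && t_trace <= tn) { tn = t_trace; kind = 2; }
      if (kind < 0) { t = tend; break; }
      t = tn;
      if (kind == 0) fireWalkClock(idx);
      else if (kind == 1) fireSSA();
      else sampleTrace();
    }
  }
};

} // namespace

// ---------------------------------------------------------------- R interface

// [[Rcpp::export(name = ".eng_create")]]
SEXP eng_create(int W, int H, double voxel_radius, double seed) {
  if (H % 2 != 0) stop("voxel row count must be even for periodic wrap");
  Engine *e = new Engine(W, H, voxel_radius, (uint64_t)seed);
  XPtr<Engine> p(e, true);
  return p;
}

// [[Rcpp::export(name = ".eng_add_species")]]
int eng_add_species(SEXP ep, std::string name, double walk_tau, bool cluster_state) {
  XPtr<Engine> e(ep);
  return e->addSpecies(name, walk_tau, cluster_state);
}

// [[Rcpp::export(name = ".eng_set_collision")]]
void eng_set_collision(SEXP ep, int a, int b, int prod_a, int prod_b, double p, int tag) {
  XPtr<Engine> e(ep);
  if (p < 0 || p > 1) stop("collision probability must lie in [0,1]");
  e->setCollision(a, b, prod_a, prod_b, p, tag);
}

// [[Rcpp::export(name = ".eng_add_first_order")]]
void eng_add_first_order(SEXP ep, int from, int to, double k, int tag) {
  XPtr<Engine> e(ep);
  e->addFirstOrder(from, to, k, tag);
}

// [[Rcpp::export(name = ".eng_add_dissociation")]]
void eng_add_dissociation(SEXP ep, int from, int to, bool uniform, double par, int tag) {
  XPtr<Engine> e(ep);
  e->addDissoc(from, to, uniform, par, tag);
}

// [[Rcpp::export(name = ".eng_place_random")]]
IntegerVector eng_place_random(SEXP ep, int spec, int count) {
  XPtr<Engine> e(ep);
  long freeVox = 0;
  for (int v = 0; v < e->nvox; ++v)
    if (!e->bitGet(e->occBit, v) && !e->bitGet(e->filBit, v)) ++freeVox;
  if (count > freeVox) stop("not enough free voxels to place %d molecules", count);
  IntegerVector ids(count);
  for (int i = 0; i < count; ++i) {
    int v;
    do { v = (int)e->rng.below((uint32_t)e->nvox); }
    while (e->bitGet(e->occBit, v) || e->bitGet(e->filBit, v));
    ids[i] = e->newMolecule(spec, v);
  }
  return ids;
}

// [[Rcpp::export(name = ".eng_place_at")]]
IntegerVector eng_place_at(SEXP ep, int spec, IntegerVector voxels) {
  XPtr<Engine> e(ep);
  IntegerVector ids(voxels.size());
  for (int i = 0; i < voxels.size(); ++i) {
    int v = voxels[i];
    if (v < 0 || v >= e->nvox) stop("voxel index out of range");
    if (e->occ[v] >= 0 && e->bitGet(e->occBit, v)) stop("voxel %d already occupied", v);
    ids[i] = e->newMolecule(spec, v);
  }
  return ids;
}

// [[Rcpp::export(name = ".eng_set_mesh")]]
void eng_set_mesh(SEXP ep, IntegerVector filament_voxels, double gap_probability) {
  XPtr<Engine> e(ep);
  std::fill(e->filBit.begin(), e->filBit.end(), 0ULL);
  for (int i = 0; i < filament_voxels.size(); ++i) {
    int v = filament_voxels[i];
    if (v < 0 || v >= e->nvox) stop("filament voxel out of range");
    e->bitSet(e->filBit, v);
  }
  e->gapp = gap_probability;
  e->meshOn = filament_voxels.size() > 0;
}

// [[Rcpp::export(name = ".eng_convert_random")]]
int eng_convert_random(SEXP ep, int from, int to, int count) {
  XPtr<Engine> e(ep);
  int done = 0;
  for (int i = 0; i < count; ++i) {
    std::vector<int32_t> &lst = e->slist[from];
    if (lst.empty()) break;
    int m = lst[e->rng.below((uint32_t)lst.size())];
    e->convert(m, to);
    ++done;
  }
  return done;
}

// [[Rcpp::export(name = ".eng_run")]]
void eng_run(SEXP ep, double duration) {
  XPtr<Engine> e(ep);
  e->run(duration);
}

// [[Rcpp::export(name = ".eng_time")]]
double eng_time(SEXP ep) { XPtr<Engine> e(ep); return e->t; }

// [[Rcpp::export(name = ".eng_counts")]]
IntegerVector eng_counts(SEXP ep) {
  XPtr<Engine> e(ep);
  IntegerVector out(e->nspec);
  CharacterVector nm(e->nspec);
  for (int s = 0; s < e->nspec; ++s) { out[s] = (int)e->slist[s].size(); nm[s] = e->sname[s]; }
  out.attr("names") = nm;
  return out;
}

// [[Rcpp::export(name = ".eng_occupancy")]]
DataFrame eng_occupancy(SEXP ep) {
  XPtr<Engine> e(ep);
  int n = (int)e->mspec.size();
  const double sy = std::sqrt(3.0) * e->rv;
  IntegerVector id(n), spec(n), vox(n), nbd(n);
  NumericVector x(n), y(n), ux(n), uy(n);
  for (int m = 0; m < n; ++m) {
    int v = e->mrow[m] * e->W + e->mcol[m];
    id[m] = m; spec[m] = e->mspec[m]; vox[m] = v;
    nbd[m] = e->nbound[m];
    x[m] = e->voxX(v); y[m] = e->voxY(v);
    ux[m] = e->upos[2 * m] * e->rv; uy[m] = e->upos[2 * m + 1] * sy;
  }
  return DataFrame::create(_["id"] = id, _["species"] = spec, _["voxel"] = vox,
                           _["x"] = x, _["y"] = y, _["ux"] = ux, _["uy"] = uy,
                           _["bound_neighbors"] = nbd);
}

// [[Rcpp::export(name = ".eng_track")]]
void eng_track(SEXP ep, IntegerVector ids, double sample_dt) {
  XPtr<Engine> e(ep);
  e->tracked.assign(ids.begin(), ids.end());
  e->trace_dt = sample_dt;
  e->t_trace = e->t;
  e->traceOn = true;
  e->traceBuf.clear();
  e->traceTimes.clear();
}

// [[Rcpp::export(name = ".eng_traces")]]
List eng_traces(SEXP ep) {
  XPtr<Engine> e(ep);
  int nt = (int)e->traceTimes.size(), nm = (int)e->tracked.size();
  NumericVector tt(e->traceTimes.begin(), e->traceTimes.end());
  NumericMatrix x(nt, nm), y(nt, nm);
  for (int i = 0; i < nt; ++i)
    for (int m = 0; m < nm; ++m) {
      x(i, m) = e->traceBuf[2 * ((size_t)i * nm + m)];
      y(i, m) = e->traceBuf[2 * ((size_t)i * nm + m) + 1];
    }
  return List::create(_["t"] = tt, _["x"] = x, _["y"] = y,
                      _["ids"] = IntegerVector(e->tracked.begin(), e->tracked.end()));
}

// [[Rcpp::export(name = ".eng_log_events")]]
void eng_log_events(SEXP ep, double t0, double t1, double max_events) {
  XPtr<Engine> e(ep);
  e->logOn = true; e->log0 = t0; e->log1 = t1; e->logMax = (size_t)max_events;
  e->logT.clear(); e->logTag.clear();
}

// [[Rcpp::export(name = ".eng_event_log")]]
DataFrame eng_event_log(SEXP ep) {
  XPtr<Engine> e(ep);
  return DataFrame::create(_["time"] = NumericVector(e->logT.begin(), e->logT.end()),
                           _["rule"] = IntegerVector(e->logTag.begin(), e->logTag.end()));
}

// [[Rcpp::export(name = ".eng_event_counts")]]
NumericVector eng_event_counts(SEXP ep) {
  XPtr<Engine> e(ep);
  return NumericVector(e->eventCount.begin(), e->eventCount.end());
}

// [[Rcpp::export(name = ".eng_collision_stats")]]
List eng_collision_stats(SEXP ep, int a, int b) {
  XPtr<Engine> e(ep);
  double att = e->colAttempt[a * (size_t)e->nspec + b] + (a == b ? 0.0 : e->colAttempt[b * (size_t)e->nspec + a]);
  double fir = e->colFire[a * (size_t)e->nspec + b] + (a == b ? 0.0 : e->colFire[b * (size_t)e->nspec + a]);
  return List::create(_["attempts"] = att, _["fired"] = fir);
}

// [[Rcpp::export(name = ".eng_neighbors")]]
IntegerMatrix eng_neighbors(SEXP ep) {
  XPtr<Engine> e(ep);
  IntegerMatrix out(e->nvox, 6);
  for (int v = 0; v < e->nvox; ++v)
    for (int d = 0; d < 6; ++d) out(v, d) = e->neighborOf(v, d);
  return out;
}

// [[Rcpp::export(name = ".eng_bound_histogram")]]
IntegerVector eng_bound_histogram(SEXP ep, IntegerVector cluster_species) {
  XPtr<Engine> e(ep);
  IntegerVector h(7);
  for (int k = 0; k < cluster_species.size(); ++k) {
    int s = cluster_species[k];
    for (int m : e->slist[s]) h[e->nbound[m]]++;
  }
  return h;
}

// [[Rcpp::export(name = ".eng_filament_voxels")]]
IntegerVector eng_filament_voxels(SEXP ep) {
  XPtr<Engine> e(ep);
  std::vector<int> out;
  for (int v = 0; v < e->nvox; ++v) if (e->bitGet(e->filBit, v)) out.push_back(v);
  return IntegerVector(out.begin(), out.end());
}
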
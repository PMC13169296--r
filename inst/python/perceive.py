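"""Molecule perception worker.

Reads one JSON request on stdin and writes one JSON response on stdout.
All chemistry perception (SMILES parsing, aromaticity, canonical ranks,
SMARTS site matching, seeded ETKDG embedding + MMFF94/UFF relaxation,
Morgan fingerprints) happens here so that the R side never re-implements
a cheminformatics primitive.

Request:
  {"seed": int, "embed": bool, "optimize_maxiters": int,
   "site_smarts": str, "fp_radius": int, "fp_bits": int, "want_fp": bool,
   "embed_retries": int,
   "records": [{"id": str, "smiles": str}, ...]}

Response: list with one object per record (same order):
  {"id", "ok", "error",
   "canonical_smiles", "n_frags", "frag_n_heavy",
   "atoms": [{"el","chg","arom","nh","ring"}...],   # explicit H appended
   "bonds": [[i, j, order, arom], ...],             # 0-based
   "ranks": [...],                                  # canonical symmetry ranks
   "sites": [...],                                  # 0-based site atom indices
   "coords": [[x,y,z],...] | None,
   "ff": "MMFF94"|"UFF"|None,
   "fp": [on-bit indices] | None}
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, rdFingerprintGenerator, rdMolDescriptors

RDLogger.DisableLog("rdApp.*")


def perceive_one(rec, opts):
    out = {"id": rec.get("id"), "ok": False, "error": None}
    smiles = rec.get("smiles", "")
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        out["error"] = "unparsable SMILES: %r" % smiles
        return out

    out["canonical_smiles"] = Chem.MolToSmiles(mol)
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
    out["n_frags"] = len(frags)
    out["frag_n_heavy"] = [f.GetNumHeavyAtoms() for f in frags]
    out["frag_smiles"] = [Chem.MolToSmiles(f) for f in frags]

    molh = Chem.AddHs(mol)
    atoms = []
    for a in molh.GetAtoms():
        atoms.append({
            "el": a.GetSymbol(),
            "chg": a.GetFormalCharge(),
            "arom": bool(a.GetIsAromatic()),
            "nh": sum(1 for n in a.GetNeighbors() if n.GetAtomicNum() == 1),
            "ring": bool(a.IsInRing()),
        })
    out["atoms"] = atoms
    out["n_heavy"] = mol.GetNumHeavyAtoms()

    bonds = []
    for b in molh.GetBonds():
        order = b.GetBondTypeAsDouble()
        bonds.append([b.GetBeginAtomIdx(), b.GetEndAtomIdx(),
                      order, bool(b.GetIsAromatic())])
    out["bonds"] = bonds

    out["ranks"] = list(Chem.CanonicalRankAtoms(molh, breakTies=False))

    patt = Chem.MolFromSmarts(opts["site_smarts"])
    if patt is None:
        out["error"] = "invalid site SMARTS: %r" % opts["site_smarts"]
        return out
    matches = molh.GetSubstructMatches(patt)
    out["sites"] = sorted({m[0] for m in matches})

    if opts.get("want_fp"):
        gen = rdFingerprintGenerator.GetMorganGenerator(
            radius=int(opts["fp_radius"]), fpSize=int(opts["fp_bits"]))
        out["fp"] = list(gen.GetFingerprint(mol).GetOnBits())

    out["coords"] = None
    out["ff"] = None
    if opts.get("embed") and molh.GetNumAtoms() > 0:
        seed = int(opts.get("seed", 2025))
        ok = -1
        for attempt in range(int(opts.get("embed_retries", 3))):
            params = AllChem.ETKDGv3()
            params.randomSeed = seed + 7919 * attempt
            params.useRandomCoords = attempt > 0
            ok = AllChem.EmbedMolecule(molh, params)
            if ok == 0:
                break
        if ok != 0:
            out["error"] = "embedding failed after retries"
            return out
        maxiters = int(opts.get("optimize_maxiters", 2000))
        props = AllChem.MMFFGetMoleculeProperties(molh)
        if props is not None and AllChem.MMFFHasAllMoleculeParams(molh):
            AllChem.MMFFOptimizeMolecule(molh, maxIters=maxiters)
            out["ff"] = "MMFF94"
        else:
            AllChem.UFFOptimizeMolecule(molh, maxIters=maxiters)
            out["ff"] = "UFF"
        conf = molh.GetConformer()
        out["coords"] = [[round(v, 9) for v in conf.GetAtomPosition(i)]
                         for i in range(molh.GetNumAtoms())]

    out["ok"] = True
    return out


def main():
    req = json.load(sys.stdin)
    opts = {
        "seed": req.get("seed", 2025),
        "embed": req.get("embed", True),
        "embed_retries": req.get("embed_retries", 3),
        "optimize_maxiters": req.get("optimize_maxiters", 2000),
        "site_smarts": req.get("site_smarts", "[cH1]"),
        "fp_radius": req.get("fp_radius", 2),
        "fp_bits": req.get("fp_bits", 2048),
        "want_fp": req.get("want_fp", False),
    }
    res = [perceive_one(rec, opts) for rec in req.get("records", [])]
    json.dump(res, sys.stdout)


if __name__ == "__main__":
    main()
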
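"""RDKit chemistry backend.

Reads a JSON job description, parses/prepares every molecule record, and
writes a JSON reply.  Called by the R package through system2(); all
communication goes through the two file arguments.

Job format:
    {"seed": int, "prepare": bool,
     "records": [{"id": str, "format": "smiles"|"sdf", "text": str}, ...]}

Reply format:
    {"rdkit_version": str,
     "molecules": [{"id", "ok", "error", "had_3d",
                    "atoms": {"element", "mass", "x", "y", "z",
                              "charge", "is_h"},
                    "bonds": {"i", "j", "order", "aromatic"},
                    "alogp", "psa"}, ...]}

Preparation = explicit hydrogens + one 3D conformer (ETKDGv3, seeded,
deterministic) + MMFF94 minimization + Gasteiger partial charges.
Records whose input already carries 3D coordinates keep them (hydrogens
are added with coordinates, no re-minimization), so that SDF geometries
supplied by the user survive.
"""

import io
import json
import math
import sys

from rdkit import Chem, rdBase
from rdkit.Chem import AllChem, Descriptors
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")

ORDER_NAMES = {
    Chem.BondType.SINGLE: "single",
    Chem.BondType.DOUBLE: "double",
    Chem.BondType.TRIPLE: "triple",
    Chem.BondType.AROMATIC: "aromatic",
}


def parse_record(rec):
    fmt = rec["format"]
    if fmt == "smiles":
        mol = Chem.MolFromSmiles(rec["text"])
        if mol is None:
            return None, "SMILES failed to parse"
        return mol, None
    if fmt == "sdf":
        supp = Chem.ForwardSDMolSupplier(
            io.BytesIO(rec["text"].encode("utf-8")), removeHs=False
        )
        try:
            mol = next(iter(supp))
        except StopIteration:
            return None, "empty SDF record"
        if mol is None:
            return None, "SDF record failed to parse"
        return mol, None
    return None, "unknown format: %s" % fmt


def has_3d(mol):
    if mol.GetNumConformers() == 0:
        return False
    conf = mol.GetConformer()
    if conf.Is3D():
        return True
    pos = conf.GetPositions()
    return any(abs(p[2]) > 1e-6 for p in pos)


def prepare(mol, mol_id, seed):
    keep = has_3d(mol)
    mol = Chem.AddHs(mol, addCoords=keep)
    if not keep:
        params = AllChem.ETKDGv3()
        params.randomSeed = int(seed)
        if AllChem.EmbedMolecule(mol, params) != 0:
            raise RuntimeError("3D embedding failed for molecule '%s'" % mol_id)
        try:
            AllChem.MMFFOptimizeMolecule(mol, maxIters=500)
        except Exception:
            AllChem.UFFOptimizeMolecule(mol, maxIters=500)
        # MMFF typing rewrites aromaticity flags with its own model;
        # re-sanitize so the default perception is reported
        Chem.SanitizeMol(mol)
    AllChem.ComputeGasteigerCharges(mol)
    return mol, keep


def atom_table(mol, prepared):
    conf = mol.GetConformer() if mol.GetNumConformers() > 0 else None
    elem, mass, xs, ys, zs, chg, ish = [], [], [], [], [], [], []
    for atom in mol.GetAtoms():
        elem.append(atom.GetSymbol())
        mass.append(atom.GetMass())
        if conf is not None:
            p = conf.GetAtomPosition(atom.GetIdx())
            xs.append(p.x)
            ys.append(p.y)
            zs.append(p.z)
        else:
            xs.append(None)
            ys.append(None)
            zs.append(None)
        if prepared:
            q = atom.GetDoubleProp("_GasteigerCharge")
            if not math.isfinite(q):
                q = 0.0
            chg.append(q)
        else:
            chg.append(None)
        ish.append(atom.GetAtomicNum() == 1)
    return {
        "element": elem,
        "mass": mass,
        "x": xs,
        "y": ys,
        "z": zs,
        "charge": chg,
        "is_h": ish,
    }


def bond_table(mol):
    ii, jj, order, arom = [], [], [], []
    for bond in mol.GetBonds():
        ii.append(bond.GetBeginAtomIdx() + 1)  # 1-based for R
        jj.append(bond.GetEndAtomIdx() + 1)
        order.append(ORDER_NAMES.get(bond.GetBondType(), "single"))
        arom.append(bond.GetIsAromatic())
    return {"i": ii, "j": jj, "order": order, "aromatic": arom}


def process(rec, seed, do_prepare):
    out = {"id": rec["id"], "ok": False, "error": None, "had_3d": False}
    mol, err = parse_record(rec)
    if mol is None:
        out["error"] = err
        return out
    # logP/TPSA are topology-only; computed on the hydrogen-suppressed graph
    base = Chem.RemoveHs(mol)
    out["alogp"] = Descriptors.MolLogP(base)
    out["psa"] = Descriptors.TPSA(base)
    prepared = False
    if do_prepare:
        try:
            mol, out["had_3d"] = prepare(mol, rec["id"], seed)
            prepared = True
        except Exception as exc:  # embedding failure
            out["error"] = str(exc)
            return out
    out["atoms"] = atom_table(mol, prepared)
    out["bonds"] = bond_table(mol)
    out["ok"] = True
    return out


def main(argv):
    with open(argv[1]) as fh:
        job = json.load(fh)
    seed = int(job.get("seed", 0))
    do_prepare = bool(job.get("prepare", False))
    mols = [process(rec, seed, do_prepare) for rec in job["records"]]
    reply = {"rdkit_version": rdBase.rdkitVersion, "molecules": mols}
    with open(argv[2], "w") as fh:
        json.dump(reply, fh)


if __name__ == "__main__":
    main(sys.argv)
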
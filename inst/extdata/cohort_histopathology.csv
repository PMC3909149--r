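group,level,finding,count,reported_percentage
malignant,total,All malignant lesions,149,63.68
malignant,subtype,Invasive ductal carcinoma,120,51.3
malignant,subtype,Intraductal carcinoma,17,7.26
malignant,subtype,Ductal carcinoma in situ,4,1.7
malignant,subtype,Mucinous carcinoma,3,1.28
malignant,subtype,Medullary carcinoma,1,0.43
malignant,subtype,Others,4,1.71
benign,total,All benign lesions,85,36.32
benign,subtype,Fibroadenoma,26,11.11
benign,subtype,Fibrocystic changes,24,10.26
benign,subtype,Fibroadenosis,3,1.28
benign,subtype,Intraductal papilloma,4,1.7
benign,subtype,Hyperplasia,3,1.28
benign,subtype,Phyllodes tumor,2,0.85
benign,subtype,Adenomyosis epithelioma,1,0.43
benign,subtype,Inflammation,1,0.43
benign,subtype,Follow-up,21,8.97
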
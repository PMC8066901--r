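"animal_id","arm","week","outcome"
"CTRL1_01","CTRL1",11,"scheduled_sacrifice"
"CTRL1_02","CTRL1",11,"scheduled_sacrifice"
"CTRL1_03","CTRL1",11,"scheduled_sacrifice"
"CTRL1_04","CTRL1",11,"scheduled_sacrifice"
"CTRL1_05","CTRL1",11,"scheduled_sacrifice"
"CTRL1_06","CTRL1",11,"scheduled_sacrifice"
"CTRL2_01","CTRL2",17,"scheduled_sacrifice"
"CTRL2_02","CTRL2",17,"scheduled_sacrifice"
"CTRL2_03","CTRL2",17,"scheduled_sacrifice"
"CTRL2_04","CTRL2",17,"scheduled_sacrifice"
"CTRL2_05","CTRL2",17,"scheduled_sacrifice"
"CTRL2_06","CTRL2",17,"scheduled_sacrifice"
"CRC1_01","CRC1",8,"spontaneous_death"
"CRC1_02","CRC1",10,"spontaneous_death"
"CRC1_03","CRC1",11,"scheduled_sacrifice"
"CRC1_04","CRC1",11,"scheduled_sacrifice"
"CRC1_05","CRC1",11,"scheduled_sacrifice"
"CRC1_06","CRC1",11,"scheduled_sacrifice"
"CRC1_07","CRC1",11,"scheduled_sacrifice"
"CRC1_08","CRC1",11,"scheduled_sacrifice"
"CRC2_01","CRC2",14,"spontaneous_death"
"CRC2_02","CRC2",16,"spontaneous_death"
"CRC2_03","CRC2",17,"spontaneous_death"
"CRC2_04","CRC2",17,"scheduled_sacrifice"
"CRC2_05","CRC2",17,"scheduled_sacrifice"
"CRC2_06","CRC2",17,"scheduled_sacrifice"
"CRC2_07","CRC2",17,"scheduled_sacrifice"
"CRC2_08","CRC2",17,"scheduled_sacrifice"
"CRC2_09","CRC2",17,"scheduled_sacrifice"
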
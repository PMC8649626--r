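index_code,other_code,relation
head,head,self
head,wife_or_husband,spouse
head,son_or_daughter,parent
head,son_or_daughter_in_law,parent_in_law
head,parent,child
head,parent_in_law,child_in_law
head,sibling,sibling
head,grandparent,grandchild
head,grandchild,grandparent
head,adopted_child,other
head,other_relative,other
head,not_related,other
head,other,other
wife_or_husband,head,spouse
wife_or_husband,wife_or_husband,self
wife_or_husband,son_or_daughter,parent
wife_or_husband,son_or_daughter_in_law,parent_in_law
wife_or_husband,parent,child_in_law
wife_or_husband,parent_in_law,child
wife_or_husband,sibling,sibling_in_law
wife_or_husband,grandparent,grandchild
wife_or_husband,grandchild,grandparent
wife_or_husband,adopted_child,other
wife_or_husband,other_relative,other
wife_or_husband,not_related,other
wife_or_husband,other,other
son_or_daughter,head,child
son_or_daughter,wife_or_husband,child
son_or_daughter,son_or_daughter,sibling
son_or_daughter,son_or_daughter_in_law,spouse_or_sibling_in_law
son_or_daughter,parent,grandchild
son_or_daughter,parent_in_law,grandchild
son_or_daughter,sibling,niece_nephew
son_or_daughter,grandparent,other
son_or_daughter,grandchild,parent_or_aunt_uncle
son_or_daughter,adopted_child,other
son_or_daughter,other_relative,other
son_or_daughter,not_related,other
son_or_daughter,other,other
son_or_daughter_in_law,head,child_in_law
son_or_daughter_in_law,wife_or_husband,child_in_law
son_or_daughter_in_law,son_or_daughter,spouse_or_sibling_in_law
son_or_daughter_in_law,son_or_daughter_in_law,sibling_in_law
son_or_daughter_in_law,parent,grandchild_in_law
son_or_daughter_in_law,parent_in_law,grandchild_in_law
son_or_daughter_in_law,sibling,niece_nephew_in_law
son_or_daughter_in_law,grandparent,other
son_or_daughter_in_law,grandchild,parent_or_aunt_uncle
son_or_daughter_in_law,adopted_child,other
son_or_daughter_in_law,other_relative,other
son_or_daughter_in_law,not_related,other
son_or_daughter_in_law,other,other
parent,head,parent
parent,wife_or_husband,parent_in_law
parent,son_or_daughter,grandparent
parent,son_or_daughter_in_law,grandparent_in_law
parent,parent,spouse
parent,parent_in_law,co_in_law
parent,sibling,parent
parent,grandparent,other
parent,grandchild,great_grandchild
parent,adopted_child,other
parent,other_relative,other
parent,not_related,other
parent,other,other
parent_in_law,head,parent_in_law
parent_in_law,wife_or_husband,parent
parent_in_law,son_or_daughter,grandparent
parent_in_law,son_or_daughter_in_law,grandparent_in_law
parent_in_law,parent,co_in_law
parent_in_law,parent_in_law,spouse_or_both_parents_in_law
parent_in_law,sibling,other_in_law
parent_in_law,grandparent,other
parent_in_law,grandchild,great_grandparent
parent_in_law,adopted_child,other
parent_in_law,other_relative,other
parent_in_law,not_related,other
parent_in_law,other,other
sibling,head,sibling
sibling,wife_or_husband,sibling_in_law
sibling,son_or_daughter,aunt_uncle
sibling,son_or_daughter_in_law,aunt_uncle_in_law
sibling,parent,child
sibling,parent_in_law,other_in_law
sibling,sibling,sibling
sibling,grandparent,other
sibling,grandchild,great_aunt_uncle
sibling,adopted_child,other
sibling,other_relative,other
sibling,not_related,other
sibling,other,other
grandparent,head,grandparent
grandparent,wife_or_husband,grandparent
grandparent,son_or_daughter,other
grandparent,son_or_daughter_in_law,other
grandparent,parent,other
grandparent,parent_in_law,other
grandparent,sibling,other
grandparent,grandparent,other
grandparent,grandchild,other
grandparent,adopted_child,other
grandparent,other_relative,other
grandparent,not_related,other
grandparent,other,other
grandchild,head,grandchild
grandchild,wife_or_husband,grandchild
grandchild,son_or_daughter,parent_or_aunt_uncle
grandchild,son_or_daughter_in_law,parent_or_aunt_uncle
grandchild,parent,great_grandchild
grandchild,parent_in_law,great_grandchild
grandchild,sibling,great_niece_nephew
grandchild,grandparent,other
grandchild,grandchild,sibling_or_cousin
grandchild,adopted_child,other
grandchild,other_relative,other
grandchild,not_related,other
grandchild,other,other
adopted_child,head,other
adopted_child,wife_or_husband,other
adopted_child,son_or_daughter,other
adopted_child,son_or_daughter_in_law,other
adopted_child,parent,other
adopted_child,parent_in_law,other
adopted_child,sibling,other
adopted_child,grandparent,other
adopted_child,grandchild,other
adopted_child,adopted_child,other
adopted_child,other_relative,other
adopted_child,not_related,other
adopted_child,other,other
other_relative,head,other
other_relative,wife_or_husband,other
other_relative,son_or_daughter,other
other_relative,son_or_daughter_in_law,other
other_relative,parent,other
other_relative,parent_in_law,other
other_relative,sibling,other
other_relative,grandparent,other
other_relative,grandchild,other
other_relative,adopted_child,other
other_relative,other_relative,other
other_relative,not_related,other
other_relative,other,other
not_related,head,other
not_related,wife_or_husband,other
not_related,son_or_daughter,other
not_related,son_or_daughter_in_law,other
not_related,parent,other
not_related,parent_in_law,other
not_related,sibling,other
not_related,grandparent,other
not_related,grandchild,other
not_related,adopted_child,other
not_related,other_relative,other
not_related,not_related,other
not_related,other,other
other,head,other
other,wife_or_husband,other
other,son_or_daughter,other
other,son_or_daughter_in_law,other
other,parent,other
other,parent_in_law,other
other,sibling,other
other,grandparent,other
other,grandchild,other
other,adopted_child,other
other,other_relative,other
other,not_related,other
other,other,other
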